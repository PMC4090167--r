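#' Read a clinical table
#'
#' Parses the study-style clinical CSV with columns `ID`, `Age`, `Grade`,
#' `TNM`, `Subtype`, `Familial`, `ER`, `PR`, `Her-2`. The combined `Grade`
#' field (`"GN3/GH2"`, `"GH2"`, `"GN3 GH2"`, `"NA"`, in either order) is
#' split into nuclear and histological grade, subtype spellings are
#' normalised, and each record's subtype is checked against the
#' receptor-proxy rules (violations are flagged in `subtype_consistent`,
#' not rejected).
#'
#' @param path Path to the clinical CSV.
#' @return Tibble of patient records: `id`, `age`, `nuclear_grade`,
#'   `histological_grade`, `stage`, `subtype`, `familial`, `er`, `pr`,
#'   `her2`, `subtype_consistent`.
#' @export
read_clinical <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  need <- c("ID", "Age", "Grade", "TNM", "Subtype", "Familial", "ER", "PR")
  if (!all(need %in% names(x))) {
    abort(paste0("clinical file lacks column(s): ",
                 paste(setdiff(need, names(x)), collapse = ", ")))
  }
  her2_col <- intersect(c("Her-2", "Her2", "HER-2"), names(x))[1]
  if (is.na(her2_col)) abort("clinical file lacks a Her-2 column.")
  if (!nrow(x)) {
    return(tibble::tibble(id = character(), age = numeric(),
                          nuclear_grade = integer(),
                          histological_grade = integer(), stage = character(),
                          subtype = character(), familial = logical(),
                          er = character(), pr = character(),
                          her2 = character(), subtype_consistent = logical()))
  }
  gn <- as.integer(stringr::str_match(x$Grade, "GN\\s*(\\d)")[, 2])
  gh <- as.integer(stringr::str_match(x$Grade, "GH\\s*(\\d)")[, 2])
  stage <- toupper(trimws(x$TNM))
  valid_stage <- c("I", "IIA", "IIB", "IIIA", "IIIB", "IV")
  if (any(!stage %in% valid_stage)) {
    abort(paste0("unknown TNM stage token(s): ",
                 paste(unique(stage[!stage %in% valid_stage]), collapse = ", ")))
  }
  subtype <- normalize_subtype(x$Subtype)
  rec <- function(v) {
    v <- toupper(trimws(gsub("\\*", "", v)))
    v[!v %in% c("POS", "NEG")] <- NA
    v
  }
  er <- rec(x$ER); pr <- rec(x$PR); her2 <- rec(x[[her2_col]])
  expected <- subtype_from_receptors(er, pr, her2)
  tibble::tibble(
    id = x$ID, age = as.numeric(x$Age),
    nuclear_grade = gn, histological_grade = gh, stage = stage,
    subtype = subtype,
    familial = grepl("\\+", x$Familial),
    er = er, pr = pr, her2 = her2,
    subtype_consistent = is.na(expected) | expected == subtype)
}

normalize_subtype <- function(s) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", s))
  out <- dplyr::case_when(
    key %in% c("LUMINALA") ~ "Luminal A",
    key %in% c("LUMINALB") ~ "Luminal B",
    key %in% c("HER2", "HER2RICH") ~ "Her-2",
    key %in% c("TRIPNEG", "TRIPLENEG", "TRIPLENEGATIVE", "TRIPNEGATIVE") ~
      "Triple negative",
    TRUE ~ NA_character_)
  if (any(is.na(out) & !is.na(s))) {
    abort(paste0("unknown subtype token(s): ",
                 paste(unique(s[is.na(out) & !is.na(s)]), collapse = ", ")))
  }
  out
}

#' Immunohistochemistry-proxy intrinsic subtype
#'
#' Applies the receptor-proxy classification: Luminal A = (ER+ and/or PR+)
#' with Her-2 negative; Luminal B = (ER+ and/or PR+) with Her-2 positive;
#' Her-2 = Her-2 positive with ER and PR negative; Triple negative = all
#' three negative. Any `NA` receptor yields an undefined subtype.
#'
#' @param er,pr,her2 Receptor calls, `"POS"`/`"NEG"` (vectorised).
#' @return Character vector of subtypes, `NA` when undefined.
#' @export
subtype_from_receptors <- function(er, pr, her2) {
  hr <- er == "POS" | pr == "POS"
  dplyr::case_when(
    is.na(er) | is.na(pr) | is.na(her2) ~ NA_character_,
    hr & her2 == "NEG" ~ "Luminal A",
    hr & her2 == "POS" ~ "Luminal B",
    !hr & her2 == "POS" ~ "Her-2",
    TRUE ~ "Triple negative")
}

#' Frequency table of clinical characteristics by group
#'
#' Dichotomises each clinical variable (stage I-II vs III-IV, histological
#' grade I-II vs III, nuclear grade II vs III, receptors positive vs
#' negative), counts per group with percentages against the group's
#' non-missing denominator, and attaches a two-sided Fisher exact p per
#' variable. `NA` values are excluded from that variable's numerator and
#' denominator.
#'
#' @param records Patient tibble from [read_clinical()]; group membership
#'   is taken from `familial` (`TRUE` = `F-BC`).
#' @return Tibble with `variable`, `category`, `n_f`, `pct_f`, `n_nf`,
#'   `pct_nf`, `n_total`, `pct_total`, `p_value` (repeated within
#'   variable).
#' @export
frequency_table <- function(records) {
  vars <- list(
    Stage = list(value = ifelse(records$stage %in% c("I", "IIA", "IIB"),
                                "I-II", "III-IV"),
                 categories = c("I-II", "III-IV")),
    `Histological grade` = list(
      value = ifelse(records$histological_grade <= 2, "I-II", "III"),
      categories = c("I-II", "III")),
    `Nuclear grade` = list(
      value = ifelse(records$nuclear_grade <= 2, "II", "III"),
      categories = c("II", "III")),
    ER = list(value = c(POS = "Positive", NEG = "Negative")[records$er],
              categories = c("Positive", "Negative")),
    PR = list(value = c(POS = "Positive", NEG = "Negative")[records$pr],
              categories = c("Positive", "Negative")),
    `Her-2` = list(value = c(POS = "Positive", NEG = "Negative")[records$her2],
                   categories = c("Positive", "Negative")))
  fam <- records$familial
  rows <- lapply(names(vars), function(vn) {
    v <- vars[[vn]]
    keep <- !is.na(v$value)
    val <- v$value[keep]; f <- fam[keep]
    n_f <- vapply(v$categories, function(cc) sum(val == cc & f), numeric(1))
    n_nf <- vapply(v$categories, function(cc) sum(val == cc & !f), numeric(1))
    p <- fisher_exact_2x2(n_f[1], n_f[2], n_nf[1], n_nf[2])
    tibble::tibble(
      variable = vn, category = v$categories,
      n_f = as.integer(n_f),
      pct_f = ifelse(sum(n_f) > 0, round_half_away(100 * n_f / sum(n_f), 1), 0),
      n_nf = as.integer(n_nf),
      pct_nf = ifelse(sum(n_nf) > 0, round_half_away(100 * n_nf / sum(n_nf), 1), 0),
      n_total = as.integer(n_f + n_nf),
      pct_total = ifelse(sum(n_f + n_nf) > 0,
                         round_half_away(100 * (n_f + n_nf) / sum(n_f + n_nf), 1), 0),
      p_value = p)
  })
  dplyr::bind_rows(rows)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities of all tables (with the observed
#' margins) no more probable than the observed one. A table with an empty
#' margin carries no information and returns p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts, column-wise:
#'   `matrix(c(a, b, c, d), 2)` i.e. rows = category, columns = group.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("cell counts must be non-negative integers.")
  }
  tab <- matrix(c(a, b, c, d), nrow = 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  fisher.test(tab)$p.value
}

#' Path to the bundled clinical transcription fixture
#'
#' Returns the packaged 36-patient clinical table (10 familial, 26
#' sporadic early-onset breast tumours) in the dialect read by
#' [read_clinical()].
#'
#' @return File path.
#' @export
clinical_fixture_path <- function() {
  system.file("extdata", "clinical_table.csv", package = "mirdcx",
              mustWork = TRUE)
}
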