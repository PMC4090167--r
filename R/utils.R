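#' Convert a wide expression tibble to a numeric matrix
#'
#' Expression tables in mirdcx are wide tibbles: the first column holds the
#' feature identifier and every remaining column is one sample.
#'
#' @param x A wide expression tibble (feature column first).
#' @return A numeric matrix with feature identifiers as row names.
#' @export
expr_matrix <- function(x) {
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Convert a numeric matrix back to a wide expression tibble
#'
#' @param m Numeric matrix with feature row names and sample column names.
#' @param id_col Name for the feature-identifier column.
#' @return A tibble with the feature column first.
#' @export
as_expr_tbl <- function(m, id_col = "feature_id") {
  tibble::as_tibble(m, rownames = id_col)
}

# Validate a two-group design against the sample columns of a wide table.
# Returns a list with per-group sample id vectors; the FIRST level is the
# numerator group of every fold change (F-BC before NF-BC when both occur).
check_design <- function(design, sample_ids = NULL) {
  stopifnot(is.data.frame(design))
  if (!all(c("sample_id", "group") %in% names(design))) {
    abort("`design` needs columns `sample_id` and `group`.")
  }
  grp <- design$group
  lev <- if (is.factor(grp)) levels(grp) else unique(as.character(grp))
  if (setequal(lev, c("F-BC", "NF-BC"))) lev <- c("F-BC", "NF-BC")
  grp <- factor(as.character(grp), levels = lev)
  if (nlevels(grp) != 2L) abort("`design` must define exactly two groups.")
  if (any(table(grp) == 0L)) abort("both groups must be non-empty.")
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, design$sample_id)
    if (length(missing)) {
      abort(paste0("samples without a group assignment: ",
                   paste(missing, collapse = ", ")))
    }
  }
  list(
    levels = lev,
    g1 = design$sample_id[grp == lev[1]],
    g2 = design$sample_id[grp == lev[2]]
  )
}

# Deterministic per-stage child seeds so pipeline stages can be re-run in
# isolation: stage k of master seed s gets (s + 7919 * k) mod (2^31 - 1).
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) + 7919 * stage_index) %% (2^31 - 1))
}

# All two-group label reassignments that preserve the original group sizes,
# as a list of index vectors for group 1; NULL when infeasibly many.
exhaustive_assignments <- function(n, n1, limit) {
  if (choose(n, n1) > limit) return(NULL)
  asplit(combn(n, n1), 2)
}

round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

trunc_digits <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p) / p
}
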