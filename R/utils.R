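# Internal helpers shared across modules.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Convert a count table to an integer-checked matrix
#'
#' Count tables throughout the package are tibbles whose first column holds the
#' feature id (promoter or window) and whose remaining columns hold one sample
#' each. This coerces to a numeric matrix with feature rownames.
#'
#' @param tbl A data frame: id column first, then numeric sample columns.
#' @param what Label used in error messages.
#' @return Numeric matrix with row names taken from the id column.
#' @keywords internal
#' @noRd
as_count_matrix <- function(tbl, what = "count table") {
  if (!is.data.frame(tbl) || ncol(tbl) < 2L) {
    abort(paste0(what, " must be a data frame with an id column and >=1 sample column"))
  }
  ids <- as.character(tbl[[1L]])
  if (anyDuplicated(ids)) abort(paste0("duplicate feature ids in ", what))
  m <- as.matrix(tbl[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort(paste0("non-numeric sample columns in ", what))
  if (anyNA(m)) abort(paste0("missing values in ", what))
  if (any(m < 0)) abort(paste0("negative counts in ", what))
  rownames(m) <- ids
  m
}

matrix_to_tbl <- function(m, id_col = "promoter_id") {
  out <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), out)
  out
}

# Accept conditions as a two-column data frame (sample, condition) or a named
# character vector; return a character vector aligned to `samples`.
condition_vector <- function(conditions, samples) {
  if (is.data.frame(conditions)) {
    if (ncol(conditions) < 2L) abort("`conditions` data frame needs columns sample, condition")
    cv <- setNames(as.character(conditions[[2L]]), as.character(conditions[[1L]]))
  } else {
    cv <- conditions
    if (is.null(names(cv)) && length(cv) == length(samples)) names(cv) <- samples
  }
  miss <- setdiff(samples, names(cv))
  if (length(miss) > 0L) {
    abort(paste0("no condition label for sample(s): ", paste(miss, collapse = ", ")))
  }
  as.character(cv[samples])
}

# Deterministic child seed, kept well below .Machine$integer.max.
child_seed <- function(seed, ...) {
  idx <- c(...)
  (as.integer(seed) + sum(as.integer(idx) * c(7919L, 104729L, 1299709L)[seq_along(idx)])) %% 2000000000L
}
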