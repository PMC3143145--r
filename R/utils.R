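# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform .data %||%
#' @importFrom stats cor fisher.test optim rbinom rexp rgamma rnorm runif rpois
#'   sd setNames var quantile
#' @importFrom utils combn head tail
NULL

VALID_RESIDUES <- c("A", "C", "G", "T", "-", "N")
BASES <- c("A", "C", "G", "T")

# Split aligned strings into a character matrix (rows = allele sequences).
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0) {
    return(matrix(character(), nrow = 0, ncol = 0))
  }
  n <- nchar(seqs)
  if (length(unique(n)) != 1) {
    abort("All sequences must have equal aligned length.")
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

collapse_char_matrix <- function(mat) {
  if (nrow(mat) == 0) return(character())
  apply(mat, 1, paste0, collapse = "")
}

# Columns to keep/normalisation under a gap-handling mode. In
# "ignore_gap_columns" mode every column containing a gap anywhere in the
# given set of sequences is removed before any comparison, which keeps
# haplotype identity transitive; in "fifth_state" mode the gap is an ordinary
# fifth character state. N is always missing data.
check_gap_mode <- function(gap_mode) {
  match.arg(gap_mode, c("ignore_gap_columns", "fifth_state"))
}

apply_gap_mode <- function(mat, gap_mode) {
  gap_mode <- check_gap_mode(gap_mode)
  if (gap_mode == "ignore_gap_columns" && ncol(mat) > 0) {
    keep <- colSums(mat == "-") == 0
    list(mat = mat[, keep, drop = FALSE], kept_columns = which(keep))
  } else {
    list(mat = mat, kept_columns = seq_len(ncol(mat)))
  }
}

# Observed states per column, excluding N (always) and optionally gaps.
column_states <- function(column, gap_is_state) {
  drop <- if (gap_is_state) "N" else c("N", "-")
  unique(column[!column %in% drop])
}

# Number of segregating sites of a character matrix under a gap mode whose
# column filtering has already been applied.
count_segregating <- function(mat, gap_is_state) {
  if (ncol(mat) == 0 || nrow(mat) == 0) return(0L)
  sum(vapply(seq_len(ncol(mat)),
             function(j) length(column_states(mat[, j], gap_is_state)) >= 2L,
             logical(1)))
}

# Pairwise absolute difference count between two character vectors with N
# treated as missing (pairwise deletion). `gap_is_state` decides whether '-'
# participates as a fifth state; when FALSE, positions where either sequence
# is gapped are skipped (used only on matrices where dataset-wide gap-column
# removal was not already performed).
pair_differences <- function(a, b, gap_is_state) {
  ok <- a != "N" & b != "N"
  if (!gap_is_state) ok <- ok & a != "-" & b != "-"
  list(diff = sum(a[ok] != b[ok]), compared = sum(ok))
}

# All unordered pairwise difference counts for a character matrix.
pairwise_diff_matrix <- function(mat, gap_is_state) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- pair_differences(mat[i, ], mat[j, ], gap_is_state)$diff
    }
  }
  d
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
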