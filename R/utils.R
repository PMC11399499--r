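# internal helpers shared across modules

#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap imap keep
NULL

# Deterministic fan-out of one user seed into per-stage child seeds.
# Kept below 2^31 so the result is always a valid R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 104729) %% 2147483629 + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}

# rank-based AUC (Mann-Whitney); labels are 0/1
rank_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

geomean <- function(x) exp(mean(log(x)))

# list_rbind() of all-NULL lists yields a 0x0 tibble; substitute a typed template
empty_as <- function(df, template) {
  if (is.null(df) || ncol(df) == 0L) template else df
}
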