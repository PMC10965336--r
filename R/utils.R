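# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive reproducible per-stage seeds from a master seed
#'
#' Random stages of the pipeline (count generation, length assignment,
#' bootstrapping) each receive their own seed so that re-running one stage
#' does not perturb the stream of another. Seeds are drawn from the master
#' seed and are always below 2^31.
#'
#' @param seed Master integer seed.
#' @param n Number of stage seeds required.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# first-crossing linear interpolation of a cumulative fraction on an
# ordered abscissa; shared by median_date() and the ground-truth oracle
.first_crossing <- function(x, cum_fraction, threshold) {
  i <- which(cum_fraction >= threshold)[1L]
  if (is.na(i)) return(NA_real_)
  if (i == 1L || cum_fraction[i] == threshold) {
    # exact hit (or the first sampled point already exceeds the threshold):
    # return the first sampled day at/above the threshold
    if (cum_fraction[i] == threshold) return(x[i])
    return(x[1L])
  }
  x[i - 1L] + (threshold - cum_fraction[i - 1L]) /
    (cum_fraction[i] - cum_fraction[i - 1L]) * (x[i] - x[i - 1L])
}

.check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
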