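#' Proportion of phenotype variance explained by one variant
#'
#' Computes, for a single variant, the share of phenotype variance explained
#' by its genotype:
#' \deqn{R^2 = \frac{2\beta^2 f(1-f)}{2\beta^2 f(1-f) + se^2 \cdot 2 n f(1-f)}}
#' with \eqn{f} the effect-allele frequency and \eqn{n} the GWAS sample
#' size. The formula is evaluated exactly as written; note the common factor
#' \eqn{2 f (1-f)} cancels algebraically, so the value equals
#' \eqn{\beta^2 / (\beta^2 + se^2 n)} — the expanded form is kept as the
#' definition and the simplification is documentation only.
#'
#' @param beta Per-allele effect estimate.
#' @param se Its standard error, > 0.
#' @param eaf Effect-allele frequency in (0, 1).
#' @param n Sample size, >= 2.
#' @return R-squared in `[0, 1)`. Vectorized over all arguments.
#' @export
#' @examples
#' variance_explained(0.1, 0.01, 0.5, 10000)  # 0.005/(0.005 + 0.5)
variance_explained <- function(beta, se, eaf, n) {
  if (any(se <= 0)) stop("se must be > 0")
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must lie in (0, 1)")
  if (any(n < 2)) stop("n must be >= 2")
  num <- 2 * beta^2 * eaf * (1 - eaf)
  den <- num + se^2 * 2 * n * eaf * (1 - eaf)
  num / den
}

#' Instrument-strength F-statistic
#'
#' \deqn{F = \frac{R^2 (n - 1 - k)}{(1 - R^2) k}}
#' where \eqn{k} is the number of variants contributing to \eqn{R^2}.
#' Instruments with F at or below 10 are conventionally considered weak.
#'
#' @param r2 Explained variance in `[0, 1)`.
#' @param n Sample size, must exceed `k + 1`.
#' @param k Number of variants in the instrument.
#' @return The F-statistic. Vectorized.
#' @export
#' @examples
#' f_statistic(0.5, 103, 1)  # 101
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)")
  if (any(n <= k + 1)) stop("n must exceed k + 1")
  r2 * (n - 1 - k) / ((1 - r2) * k)
}

#' Select genetic instruments for an exposure
#'
#' Applies the instrument-selection cascade: keep variants with
#' `pvalue < p_threshold`, prune to approximate LD independence by greedy
#' clumping (`r2 < r2_clump` within `window_kb`), compute per-variant
#' explained variance and F (with k = 1), and drop weak instruments with
#' `F <= f_min` (the boundary F = `f_min` itself is excluded). The aggregate
#' F over the survivors is computed from the summed per-variant R-squared
#' with k equal to the surviving count and n the minimum sample size among
#' survivors.
#'
#' @param exposure A [sumstat_set()].
#' @param ld An `ld_matrix` or `NULL`.
#' @param p_threshold Significance threshold (e.g. `1e-5` forward,
#'   `5e-8` for reverse-direction instruments).
#' @param f_min Weak-instrument bound; keep requires F strictly greater.
#' @param r2_clump,window_kb Clumping parameters, see [clump()].
#' @param n_default Fallback sample size when a variant's `n` is missing.
#' @return An `instrument_set`: list with the selected `records` (canonical
#'   columns plus `r2` and `f`), `aggregate_f`, `thresholds`, and an
#'   `attrition` data frame counting exclusions per stage.
#' @export
select_instruments <- function(exposure, ld = NULL, p_threshold = 1e-5,
                               f_min = 10, r2_clump = 0.001,
                               window_kb = 10000, n_default = NULL) {
  stopifnot(inherits(exposure, "sumstat_set"))
  r0 <- exposure$records
  attrition <- data.frame(stage = character(), excluded = integer(),
                          remaining = integer(), stringsAsFactors = FALSE)
  note <- function(stage, before, after) {
    attrition <<- rbind(attrition,
                        data.frame(stage = stage, excluded = before - after,
                                   remaining = after, stringsAsFactors = FALSE))
  }
  sig <- r0[r0$pvalue < p_threshold, , drop = FALSE]
  note("p_threshold", nrow(r0), nrow(sig))
  if (nrow(sig) == 0L)
    stop(empty_instrument_error("no variants pass the significance threshold",
                                attrition))
  tmp <- exposure; tmp$records <- sig
  clumped <- clump(tmp, ld, r2_threshold = r2_clump, window_kb = window_kb)
  rc <- clumped$records
  note("ld_clump", nrow(sig), nrow(rc))
  nvec <- rc$n
  if (anyNA(nvec)) {
    if (is.null(n_default))
      n_default <- exposure$provenance$n_default
    if (is.null(n_default))
      stop("variants lack sample size and no n_default is available")
    message(sum(is.na(nvec)), " variant(s) use the set-level default n = ",
            n_default)
    nvec[is.na(nvec)] <- n_default
  }
  rc$n <- nvec
  rc$r2 <- variance_explained(rc$beta, rc$se, rc$eaf, rc$n)
  rc$f <- f_statistic(rc$r2, rc$n, k = 1)
  strong <- rc[rc$f > f_min, , drop = FALSE]
  note("weak_f", nrow(rc), nrow(strong))
  if (nrow(strong) == 0L)
    stop(empty_instrument_error("no variants survive the weak-instrument filter",
                                attrition))
  rownames(strong) <- NULL
  k <- nrow(strong)
  agg_r2 <- sum(strong$r2)
  agg_n <- min(strong$n)
  aggregate_f <- if (agg_n > k + 1 && agg_r2 < 1)
    f_statistic(agg_r2, agg_n, k = k) else NA_real_
  structure(list(trait_id = exposure$trait_id,
                 records = strong,
                 aggregate_f = aggregate_f,
                 thresholds = list(p_threshold = p_threshold, f_min = f_min,
                                   r2_clump = r2_clump, window_kb = window_kb),
                 attrition = attrition),
            class = "instrument_set")
}

empty_instrument_error <- function(msg, attrition) {
  structure(class = c("empty_instrument_error", "error", "condition"),
            list(message = paste0(msg, "\nattrition:\n",
                                  paste(utils::capture.output(print(attrition)),
                                        collapse = "\n")),
                 call = sys.call(-1), attrition = attrition))
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> trait '%s': %d instruments, aggregate F = %.2f\n",
              x$trait_id, nrow(x$records), x$aggregate_f))
  invisible(x)
}

#' Serialize an instrument set
#'
#' Writes the selected variants (canonical columns plus per-variant `r2` and
#' `f`) as TSV, with a JSON sidecar (`<path>.json`) holding the thresholds,
#' the aggregate F and the stage-by-stage attrition counts.
#'
#' @param iv An `instrument_set`.
#' @param path Output TSV path.
#' @export
write_instruments <- function(iv, path) {
  utils::write.table(iv$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- list(trait_id = iv$trait_id, thresholds = iv$thresholds,
               aggregate_f = iv$aggregate_f, attrition = iv$attrition)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# Convert an instrument_set back to a sumstat_set (for harmonization).
instruments_as_sumstats <- function(iv, trait_type = "quantitative") {
  sumstat_set(iv$trait_id,
              iv$records[, CANONICAL_COLS, drop = FALSE],
              trait_type = trait_type)
}
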