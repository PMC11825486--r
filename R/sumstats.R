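CANONICAL_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pvalue", "n")

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Column-name presets for common summary-statistic dialects
#'
#' Returns a named character vector mapping canonical field names to the
#' column names used by a known file dialect. `"canonical"` is the package's
#' own schema; `"finngen"` matches FinnGen release headers (which carry no
#' per-variant sample size, so `n` must be supplied via `n_default` when
#' reading).
#'
#' @param preset One of `"canonical"`, `"finngen"`.
#' @return Named character vector, names are canonical fields, values are
#'   file column names.
#' @export
#' @examples
#' column_preset("finngen")
column_preset <- function(preset = c("canonical", "finngen")) {
  preset <- match.arg(preset)
  switch(preset,
    canonical = stats::setNames(CANONICAL_COLS, CANONICAL_COLS),
    finngen = c(snp_id = "rsids", chrom = "#chrom", pos = "pos",
                effect_allele = "alt", other_allele = "ref",
                eaf = "af_alt", beta = "beta", se = "sebeta",
                pvalue = "pval", n = "n")
  )
}

#' Construct a summary-statistic set
#'
#' A `sumstat_set` bundles per-variant association records for one trait:
#' one row per SNP with alleles, effect-allele frequency, effect size,
#' standard error, p-value and sample size. Betas are log odds ratios for
#' binary traits and SD units for quantitative traits.
#'
#' @param trait_id Character scalar naming the trait.
#' @param records Data frame with the canonical columns
#'   `snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
#'   pvalue, n`.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param provenance Optional named list of free-text metadata.
#' @return An object of class `sumstat_set`.
#' @export
sumstat_set <- function(trait_id, records, trait_type = c("quantitative", "binary"),
                        provenance = list()) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_id), length(trait_id) == 1L)
  missing_cols <- setdiff(CANONICAL_COLS, names(records))
  if (length(missing_cols))
    stop("records missing canonical column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(records$snp_id))
    stop("duplicate snp_id in records for trait ", trait_id)
  rownames(records) <- NULL
  structure(list(trait_id = trait_id, trait_type = trait_type,
                 records = records[, CANONICAL_COLS, drop = FALSE],
                 provenance = provenance),
            class = "sumstat_set")
}

#' @export
print.sumstat_set <- function(x, ...) {
  cat(sprintf("<sumstat_set> trait '%s' (%s), %d variants\n",
              x$trait_id, x$trait_type, nrow(x$records)))
  invisible(x)
}

# Validate raw rows against the per-variant invariants; returns a list with
# the kept data.frame and a named vector of drop counts by reason.
validate_records <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  mark <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  ea <- toupper(as.character(df$effect_allele))
  oa <- toupper(as.character(df$other_allele))
  mark(is.na(df$snp_id) | df$snp_id == "" | is.na(df$beta) | is.na(df$se) |
         is.na(df$eaf) | is.na(df$pvalue) | is.na(df$n) | is.na(ea) | is.na(oa),
       "missing_value")
  mark(!(ea %in% BASES) | !(oa %in% BASES), "non_snp_allele")
  mark(ea == oa, "identical_alleles")
  mark(df$se <= 0, "nonpositive_se")
  mark(df$eaf <= 0 | df$eaf >= 1, "eaf_out_of_range")
  mark(df$pvalue <= 0 | df$pvalue > 1, "pvalue_out_of_range")
  mark(df$n < 1 | df$n != round(df$n), "bad_sample_size")
  keep <- is.na(reason)
  df$effect_allele <- ea
  df$other_allele <- oa
  list(kept = df[keep, , drop = FALSE],
       dropped = table(factor(reason[!keep])))
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited file (gzip-transparent) with a header row,
#' renames columns to the canonical schema via `column_map`, validates every
#' row against the variant invariants (single-base distinct alleles, positive
#' SE, frequency and p-value in range), and drops offending rows with
#' counted reasons. The parse report (rows read / kept / dropped by reason)
#' is stored in the returned set's `provenance$parse_report`.
#'
#' @param path File path; `.gz` files are decompressed on the fly.
#' @param column_map Named character vector mapping canonical fields to file
#'   columns, e.g. from [column_preset()]. Mandatory fields are all canonical
#'   fields except `n` (see `n_default`).
#' @param trait_id Trait identifier; defaults to the file name sans extension.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param n_default Sample size to fill in when the file lacks an `n` column
#'   (FinnGen-style); its use is recorded in the parse report.
#' @return A [sumstat_set()].
#' @export
read_sumstats <- function(path, column_map = column_preset("canonical"),
                          trait_id = NULL,
                          trait_type = c("quantitative", "binary"),
                          n_default = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!length(first)) stop("empty input file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  close(con); on.exit(NULL)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  raw <- utils::read.table(con, header = TRUE, sep = sep, quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  n_read <- nrow(raw)
  have_n <- !is.na(column_map["n"]) && column_map[["n"]] %in% names(raw)
  mandatory <- setdiff(CANONICAL_COLS, "n")
  for (f in mandatory) {
    if (is.na(column_map[f]) || !(column_map[[f]] %in% names(raw)))
      stop("mandatory column for field '", f, "' not found in ", path,
           " (expected file column '", column_map[f], "')")
  }
  df <- data.frame(snp_id = as.character(raw[[column_map[["snp_id"]]]]),
                   chrom = as.character(raw[[column_map[["chrom"]]]]),
                   pos = as.integer(raw[[column_map[["pos"]]]]),
                   effect_allele = as.character(raw[[column_map[["effect_allele"]]]]),
                   other_allele = as.character(raw[[column_map[["other_allele"]]]]),
                   eaf = as.numeric(raw[[column_map[["eaf"]]]]),
                   beta = as.numeric(raw[[column_map[["beta"]]]]),
                   se = as.numeric(raw[[column_map[["se"]]]]),
                   pvalue = as.numeric(raw[[column_map[["pvalue"]]]]),
                   n = if (have_n) as.numeric(raw[[column_map[["n"]]]])
                       else rep(if (is.null(n_default)) NA_real_ else n_default, n_read),
                   stringsAsFactors = FALSE)
  val <- validate_records(df)
  kept <- val$kept
  if (anyDuplicated(kept$snp_id)) {
    dup <- duplicated(kept$snp_id)
    val$dropped <- c(val$dropped, duplicate_snp_id = sum(dup))
    kept <- kept[!dup, , drop = FALSE]
  }
  if (nrow(kept) == 0L)
    stop("no valid summary-statistic rows in ", path)
  if (is.null(trait_id))
    trait_id <- sub("\\.(tsv|csv|txt)(\\.gz)?$", "", basename(path))
  report <- list(rows_read = n_read, rows_kept = nrow(kept),
                 dropped = as.list(val$dropped),
                 n_default_used = !have_n)
  sumstat_set(trait_id, kept, trait_type,
              provenance = list(path = path, parse_report = report,
                                n_default = n_default))
}

#' Write a summary-statistic set as canonical TSV
#'
#' @param set A [sumstat_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(set, path) {
  utils::write.table(set$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a square LD matrix
#'
#' The on-disk format is a square TSV with snp_id as both the header row and
#' the first column; entries are pairwise r-squared values in `[0, 1]` with a
#' unit diagonal.
#'
#' @param path File path.
#' @return For `read_ld_matrix`, an `ld_matrix` object (numeric matrix with
#'   snp_id dimnames).
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = 1L)
  ld_matrix(as.matrix(raw))
}

#' @rdname read_ld_matrix
#' @param ld An `ld_matrix`.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(snp_id = rownames(ld), unclass(ld), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated LD matrix
#'
#' @param r2 Square numeric matrix of pairwise LD r-squared values with
#'   snp_id dimnames.
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(r2) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) stop("LD matrix must be square")
  if (is.null(rownames(r2)) || is.null(colnames(r2)))
    stop("LD matrix needs snp_id dimnames")
  if (!identical(rownames(r2), colnames(r2)))
    stop("LD matrix row and column snp_ids differ")
  if (any(r2 < 0 | r2 > 1)) stop("LD r2 entries must lie in [0, 1]")
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("LD matrix diagonal must be 1")
  if (any(abs(r2 - t(r2)) > 1e-8)) stop("LD matrix must be symmetric")
  structure(r2, class = c("ld_matrix", "matrix", "array"))
}

#' Identity LD matrix for a set of variants
#'
#' @param snp_ids Character vector of variant identifiers.
#' @return An `ld_matrix` with zero off-diagonal LD.
#' @export
ld_identity <- function(snp_ids) {
  m <- diag(length(snp_ids))
  dimnames(m) <- list(snp_ids, snp_ids)
  ld_matrix(m)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize summary-statistic sets to a shared effect allele
#'
#' Aligns two or three trait sets on their shared variants so that every
#' trait reports effects for the same effect allele, the primary set's.
#' In non-primary sets a swapped allele pair flips the sign of beta and
#' replaces eaf by 1 - eaf; strand complements (A<->T, C<->G) are resolved
#' before comparison. Palindromic variants (A/T or G/C), whose strand cannot
#' be determined from alleles, are kept only when every trait's aligned eaf
#' falls outside `0.5 +/- palindromic_eaf_window` and all aligned eafs lie on
#' the same side of 0.5; otherwise they are dropped with reason
#' `palindromic_ambiguous`. Irreconcilable allele pairs are dropped with
#' reason `allele_mismatch`; variants absent from any set with reason
#' `missing_in_other_trait`.
#'
#' @param primary A [sumstat_set()] defining the reference effect allele
#'   (conventionally the exposure).
#' @param others A single [sumstat_set()] or list of one or two sets.
#' @param palindromic_eaf_window Half-width of the frequency window around
#'   0.5 inside which palindromic variants are considered ambiguous.
#' @return A `harmonized_set`: list with `snp_ids`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `trait_ids`, `beta`/`se`/`eaf`/`n`
#'   matrices (one column per trait, primary first), and a `dropped` data
#'   frame of `(snp_id, reason)`.
#' @export
harmonize <- function(primary, others, palindromic_eaf_window = 0.08) {
  if (inherits(others, "sumstat_set")) others <- list(others)
  stopifnot(length(others) %in% 1:2,
            all(vapply(others, inherits, TRUE, "sumstat_set")))
  sets <- c(list(primary), others)
  ids <- lapply(sets, function(s) s$records$snp_id)
  shared <- Reduce(intersect, ids)
  if (!length(shared))
    stop("no snp_id shared by all summary-statistic sets")
  all_ids <- unique(unlist(ids))
  miss <- setdiff(all_ids, shared)
  dropped <- data.frame(snp_id = miss,
                        reason = rep("missing_in_other_trait", length(miss)),
                        stringsAsFactors = FALSE)

  recs <- lapply(sets, function(s) {
    r <- s$records
    r[match(shared, r$snp_id), , drop = FALSE]
  })
  p <- recs[[1L]]
  k <- length(shared)
  nt <- length(sets)
  beta <- se <- eaf <- nmat <- matrix(NA_real_, k, nt)
  beta[, 1L] <- p$beta; se[, 1L] <- p$se; eaf[, 1L] <- p$eaf; nmat[, 1L] <- p$n
  drop_reason <- rep(NA_character_, k)
  pal <- is_palindromic(p$effect_allele, p$other_allele)

  for (t in 2:nt) {
    r <- recs[[t]]
    ea <- r$effect_allele; oa <- r$other_allele
    same <- ea == p$effect_allele & oa == p$other_allele
    swap <- ea == p$other_allele & oa == p$effect_allele
    cea <- unname(COMPLEMENT[ea]); coa <- unname(COMPLEMENT[oa])
    same_c <- !same & !swap & cea == p$effect_allele & coa == p$other_allele
    swap_c <- !same & !swap & cea == p$other_allele & coa == p$effect_allele
    flip <- swap | swap_c
    ok <- same | swap | same_c | swap_c
    drop_reason[!ok & is.na(drop_reason)] <- "allele_mismatch"
    b <- ifelse(flip, -r$beta, r$beta)
    f <- ifelse(flip, 1 - r$eaf, r$eaf)
    beta[, t] <- b; se[, t] <- r$se; eaf[, t] <- f; nmat[, t] <- r$n
  }

  # palindromic rule applied on aligned frequencies across every trait
  if (any(pal)) {
    lo <- 0.5 - palindromic_eaf_window
    hi <- 0.5 + palindromic_eaf_window
    in_window <- apply(eaf >= lo & eaf <= hi, 1L, any)
    side <- sign(eaf - 0.5)
    agree <- apply(side, 1L, function(z) all(z == z[1L]))
    bad_pal <- pal & (in_window | !agree)
    drop_reason[bad_pal & is.na(drop_reason)] <- "palindromic_ambiguous"
  }

  keep <- is.na(drop_reason)
  if (any(!keep))
    dropped <- rbind(dropped,
                     data.frame(snp_id = shared[!keep],
                                reason = drop_reason[!keep],
                                stringsAsFactors = FALSE))
  if (!any(keep)) stop("no variants survive harmonization")
  trait_ids <- vapply(sets, `[[`, "", "trait_id")
  dimnames(beta) <- dimnames(se) <- dimnames(eaf) <- dimnames(nmat) <-
    list(shared, trait_ids)
  structure(list(snp_ids = shared[keep],
                 chrom = p$chrom[keep], pos = p$pos[keep],
                 effect_allele = p$effect_allele[keep],
                 other_allele = p$other_allele[keep],
                 trait_ids = trait_ids,
                 beta = beta[keep, , drop = FALSE],
                 se = se[keep, , drop = FALSE],
                 eaf = eaf[keep, , drop = FALSE],
                 n = nmat[keep, , drop = FALSE],
                 dropped = dropped),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %d variants x %d traits (%s); %d dropped\n",
              length(x$snp_ids), length(x$trait_ids),
              paste(x$trait_ids, collapse = ", "), nrow(x$dropped)))
  invisible(x)
}

#' Write the harmonization drop report
#'
#' @param h A `harmonized_set`.
#' @param path Output TSV path (`snp_id`, `reason`).
#' @export
write_drop_report <- function(h, path) {
  utils::write.table(h$dropped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Restrict a harmonized set to a subset of snp_ids (order preserved).
subset_harmonized <- function(h, ids) {
  idx <- match(ids, h$snp_ids)
  stopifnot(!anyNA(idx))
  h$snp_ids <- h$snp_ids[idx]
  h$chrom <- h$chrom[idx]; h$pos <- h$pos[idx]
  h$effect_allele <- h$effect_allele[idx]
  h$other_allele <- h$other_allele[idx]
  for (f in c("beta", "se", "eaf", "n")) h[[f]] <- h[[f]][idx, , drop = FALSE]
  h
}

# Pairwise LD lookup with missing-variant fallback r2 = 0 (logged once).
ld_lookup <- function(ld, id1, id2) {
  if (is.null(ld)) return(0)
  present <- rownames(ld)
  if (!(id1 %in% present) || !(id2 %in% present)) return(0)
  ld[id1, id2]
}

#' Greedy LD clumping
#'
#' Repeatedly selects the remaining variant with the smallest p-value (ties
#' broken by lexicographic snp_id) as an index variant and discards all
#' remaining variants on the same chromosome within `window_kb` of it whose
#' LD r-squared with the index exceeds `r2_threshold`. Variants absent from
#' the LD matrix are treated as unlinked (r2 = 0) with a warning.
#'
#' @param set A [sumstat_set()].
#' @param ld An `ld_matrix` (or `NULL` for all-independent).
#' @param r2_threshold LD pruning threshold, default 0.001.
#' @param window_kb Clumping window in kilobases around the index variant,
#'   default 10000 (i.e. +/- 10 Mb).
#' @return A [sumstat_set()] containing the selected index variants only.
#' @export
clump <- function(set, ld = NULL, r2_threshold = 0.001, window_kb = 10000) {
  r <- set$records
  if (nrow(r) <= 1L) return(set)
  if (!is.null(ld)) {
    missing_ld <- setdiff(r$snp_id, rownames(ld))
    if (length(missing_ld))
      warning(length(missing_ld),
              " variant(s) absent from LD matrix treated as unlinked (r2=0)")
  }
  ord <- order(r$pvalue, r$snp_id)
  r <- r[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(r))
  keep <- logical(nrow(r))
  win <- window_kb * 1000
  for (i in seq_len(nrow(r))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & r$chrom == r$chrom[i] & abs(r$pos - r$pos[i]) <= win)
    if (length(cand)) {
      r2s <- vapply(cand, function(j) ld_lookup(ld, r$snp_id[i], r$snp_id[j]), 0)
      alive[cand[r2s > r2_threshold]] <- FALSE
    }
  }
  kept_ids <- r$snp_id[keep]
  out <- set
  out$records <- set$records[set$records$snp_id %in% kept_ids, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}
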