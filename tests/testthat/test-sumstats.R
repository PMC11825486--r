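test_that("read_sumstats keeps valid rows and drops invalid ones with reasons", {
  df <- make_records(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                     se = 0.02)
  path <- write_fixture_tsv(df)
  s <- read_sumstats(path)
  expect_s3_class(s, "sumstat_set")
  expect_equal(nrow(s$records), 3L)
  expect_equal(s$provenance$parse_report$rows_kept, 3L)
  expect_length(s$provenance$parse_report$dropped, 0L)

  df_bad <- df
  df_bad$se[2] <- 0
  s2 <- read_sumstats(write_fixture_tsv(df_bad))
  expect_equal(nrow(s2$records), 2L)
  expect_equal(s2$provenance$parse_report$dropped$nonpositive_se, 1L)

  df_indel <- df
  df_indel$effect_allele[1] <- "AT"
  df_indel$other_allele[1] <- "A"
  s3 <- read_sumstats(write_fixture_tsv(df_indel))
  expect_equal(nrow(s3$records), 2L)
  expect_equal(s3$provenance$parse_report$dropped$non_snp_allele, 1L)
  expect_false("rs1" %in% s3$records$snp_id)
})

test_that("read_sumstats errors on missing mandatory columns and empty input", {
  df <- make_records("rs1", beta = 0.1, se = 0.02)
  df$eaf <- NULL
  expect_error(read_sumstats(write_fixture_tsv(df)), "eaf")
  df2 <- make_records("rs1", beta = 0.1, se = -1)
  expect_error(read_sumstats(write_fixture_tsv(df2)), "no valid")
})

test_that("read_sumstats is gzip-transparent and honours the finngen preset", {
  df <- make_records(c("rs1", "rs2"), beta = c(0.1, 0.2), se = 0.02)
  fg <- data.frame(`#chrom` = df$chrom, pos = df$pos, ref = df$other_allele,
                   alt = df$effect_allele, rsids = df$snp_id,
                   pval = df$pvalue, beta = df$beta, sebeta = df$se,
                   af_alt = df$eaf, check.names = FALSE)
  path <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(path, "w")
  utils::write.table(fg, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  s <- read_sumstats(path, column_map = column_preset("finngen"),
                     trait_type = "binary", n_default = 321040)
  expect_equal(s$records$beta, df$beta)
  expect_true(all(s$records$n == 321040))
  expect_true(s$provenance$parse_report$n_default_used)
})

test_that("harmonize aligns, swap-flips, and resolves strand complements", {
  p <- make_set("x", c("rs1", "rs2", "rs3"), beta = c(0.10, 0.10, 0.10),
                se = 0.02, eaf = 0.30)
  o_rec <- make_records(c("rs1", "rs2", "rs3"), beta = c(-0.05, -0.05, -0.05),
                        se = 0.03, eaf = 0.30)
  # rs2: swapped alleles; rs3: strand-complement swapped (G/A -> C/T)
  o_rec$effect_allele <- c("A", "G", "C")
  o_rec$other_allele <- c("G", "A", "T")
  o_rec$eaf <- c(0.30, 0.70, 0.70)
  o <- sumstat_set("y", o_rec)
  h <- harmonize(p, o)
  expect_equal(h$snp_ids, c("rs1", "rs2", "rs3"))
  expect_equal(unname(h$beta[, 2]), c(-0.05, 0.05, 0.05))
  expect_equal(unname(h$eaf[, 2]), c(0.30, 0.30, 0.30))
  expect_equal(nrow(h$dropped), 0L)
})

test_that("irreconcilable alleles and one-sided variants are dropped with reasons", {
  p <- make_set("x", c("rs1", "rs2", "rs4"), beta = c(0.1, 0.1, 0.1), se = 0.02)
  o_rec <- make_records(c("rs1", "rs2", "rs3"), beta = c(0.05, 0.05, 0.05),
                        se = 0.02)
  o_rec$effect_allele <- c("A", "A", "A")
  o_rec$other_allele <- c("C", "G", "G")  # rs1 A/C cannot match primary A/G
  o <- sumstat_set("y", o_rec)
  h <- harmonize(p, o)
  expect_equal(h$snp_ids, "rs2")
  reasons <- h$dropped$reason[match(c("rs1", "rs3", "rs4"), h$dropped$snp_id)]
  expect_equal(reasons, c("allele_mismatch", "missing_in_other_trait",
                          "missing_in_other_trait"))
  # every input variant accounted for exactly once
  expect_setequal(c(h$snp_ids, h$dropped$snp_id),
                  union(p$records$snp_id, o$records$snp_id))
})

test_that("palindromic variants follow the frequency-window rule", {
  mk <- function(eaf_p, eaf_o, ea_o = "A", oa_o = "T") {
    p <- make_set("x", "rs1", beta = 0.1, se = 0.02, eaf = eaf_p,
                  effect_allele = "A", other_allele = "T")
    o_rec <- make_records("rs1", beta = 0.05, se = 0.02, eaf = eaf_o,
                          effect_allele = ea_o, other_allele = oa_o)
    harmonize(p, sumstat_set("y", o_rec))
  }
  # eaf 0.5 sits inside [0.42, 0.58] -> ambiguous
  expect_error(mk(0.5, 0.5), "survive")
  # clear frequencies on the same side -> retained
  h <- mk(0.2, 0.25)
  expect_equal(h$snp_ids, "rs1")
  # clear frequencies on opposite sides after alignment -> dropped
  expect_error(mk(0.2, 0.8), "survive")
})

test_that("harmonize is idempotent and sign-flip symmetric", {
  set.seed(4)
  k <- 8
  p <- make_set("x", sprintf("rs%d", 1:k), beta = rnorm(k, 0, 0.1), se = 0.02,
                eaf = runif(k, 0.1, 0.45))
  o <- make_set("y", sprintf("rs%d", 1:k), beta = rnorm(k, 0, 0.1), se = 0.03,
                eaf = runif(k, 0.1, 0.45))
  h1 <- harmonize(p, o)
  # rebuild sets from the harmonized arrays and harmonize again
  rebuild <- function(h, col, id) {
    r <- make_records(h$snp_ids, beta = h$beta[, col], se = h$se[, col],
                      eaf = h$eaf[, col])
    r$effect_allele <- h$effect_allele
    r$other_allele <- h$other_allele
    sumstat_set(id, r)
  }
  h2 <- harmonize(rebuild(h1, 1, "x"), rebuild(h1, 2, "y"))
  expect_equal(h2$beta, h1$beta, ignore_attr = TRUE)
  expect_equal(h2$eaf, h1$eaf, ignore_attr = TRUE)

  # flipping the other set's alleles and beta sign leaves output identical
  o_flip <- o
  tmp <- o_flip$records$effect_allele
  o_flip$records$effect_allele <- o_flip$records$other_allele
  o_flip$records$other_allele <- tmp
  o_flip$records$beta <- -o_flip$records$beta
  o_flip$records$eaf <- 1 - o_flip$records$eaf
  h3 <- harmonize(p, o_flip)
  expect_equal(h3$beta, h1$beta, ignore_attr = TRUE)
})

test_that("greedy clumping keeps the strongest independent variants", {
  ids <- c("rsA", "rsB", "rsC")
  s <- make_set("x", ids, beta = c(0.3, 0.2, 0.1), se = 0.02,
                pvalue = c(1e-8, 1e-6, 1e-5), pos = c(1e6, 2e6, 3e6))
  r2 <- diag(3)
  dimnames(r2) <- list(ids, ids)
  r2["rsA", "rsB"] <- r2["rsB", "rsA"] <- 0.5
  r2["rsA", "rsC"] <- r2["rsC", "rsA"] <- 0.0004
  ld <- ld_matrix(r2)
  out <- clump(s, ld)
  expect_setequal(out$records$snp_id, c("rsA", "rsC"))

  # all independent -> identity
  out2 <- clump(s, ld_identity(ids))
  expect_equal(nrow(out2$records), 3L)

  # perfect LD, tied p -> lexicographically smaller id survives
  s2 <- make_set("x", c("rsZ", "rsY"), beta = c(0.1, 0.1), se = 0.02,
                 pvalue = c(1e-6, 1e-6), pos = c(1e6, 1.5e6))
  r2b <- matrix(1, 2, 2, dimnames = list(c("rsZ", "rsY"), c("rsZ", "rsY")))
  out3 <- clump(s2, ld_matrix(r2b))
  expect_equal(out3$records$snp_id, "rsY")
})

test_that("clumping is invariant to input row order and respects the window", {
  set.seed(9)
  k <- 12
  ids <- sprintf("rs%02d", 1:k)
  s <- make_set("x", ids, beta = rnorm(k, 0.2, 0.02), se = 0.02,
                pvalue = runif(k, 1e-9, 1e-5), pos = (1:k) * 3e6)
  r2 <- abs(stats::toeplitz(c(1, 0.4, 0.2, rep(0.0005, k - 3))))
  dimnames(r2) <- list(ids, ids)
  ld <- ld_matrix(r2)
  a <- clump(s, ld)
  s_shuf <- s
  s_shuf$records <- s$records[sample(k), ]
  b <- clump(s_shuf, ld)
  expect_setequal(a$records$snp_id, b$records$snp_id)

  # identical pair in perfect LD but beyond the window is NOT pruned
  far <- make_set("x", c("rs1", "rs2"), beta = c(0.2, 0.2), se = 0.02,
                  pvalue = c(1e-8, 1e-7), pos = c(1e6, 3e10))
  r2f <- matrix(1, 2, 2, dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  expect_equal(nrow(clump(far, ld_matrix(r2f))$records), 2L)

  # variants missing from the LD matrix are treated as unlinked, with warning
  expect_warning(out <- clump(s, ld_identity(ids[1:3])), "absent")
  expect_equal(nrow(out$records), k)
})

test_that("LD matrix round-trips through TSV and validates its invariants", {
  ld <- ld_identity(c("rs1", "rs2", "rs3"))
  path <- tempfile(fileext = ".tsv")
  write_ld_matrix(ld, path)
  back <- read_ld_matrix(path)
  expect_equal(unclass(back), unclass(ld), ignore_attr = TRUE)
  bad <- matrix(c(1, 0.5, 0.4, 1), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(ld_matrix(bad), "symmetric")
})
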