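test_that("summary statistics round-trip through TSV and reject bad rows", {
  stats <- make_sumstats(c("rs1", "rs2"), c(100L, 200L), c("A", "C"), c("G", "T"),
                         beta = c(0.2, -0.05), se = c(0.02, 0.01))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(stats, path)
  back <- read_sumstats(path)
  expect_equal(as.data.frame(back), as.data.frame(stats))

  # dialect remap of header names
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  names(raw)[names(raw) == "SNP"] <- "rsid"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(raw, path2)
  expect_error(read_sumstats(path2), class = "targetmr_format_error")
  expect_equal(read_sumstats(path2, dialect = c(variant_id = "rsid"))$variant_id,
               stats$variant_id)

  bad <- stats
  bad$se[2] <- 0
  expect_error(validate_sumstats(bad), "row 2.*se", class = "targetmr_validation_error")
  bad <- stats
  bad$p[1] <- 0
  expect_error(validate_sumstats(bad), class = "targetmr_validation_error")
  bad <- stats
  bad$other_allele[1] <- "A"
  expect_error(validate_sumstats(bad), class = "targetmr_validation_error")
})

test_that("LD matrix reader validates shape, symmetrizes tiny asymmetries, round-trips", {
  pm <- withr::local_tempfile()
  pi <- withr::local_tempfile()
  writeLines(c("1 0.5", "0.5 1"), pm)
  writeLines(c("rs1", "rs2"), pi)
  r <- read_ld_matrix(pm, pi)
  expect_equal(r["rs1", "rs2"], 0.5)
  expect_identical(rownames(r), c("rs1", "rs2"))

  # averaging of sub-tolerance asymmetry
  writeLines(c("1 0.5", paste(0.5 + 1e-9, 1)), pm)
  r <- read_ld_matrix(pm, pi)
  expect_equal(r[1, 2], 0.5 + 5e-10, tolerance = 1e-15)
  expect_identical(r[1, 2], r[2, 1])

  # non-square and dimension mismatch are format errors
  writeLines(c("1 0.5", "0.5 1", "0 0"), pm)
  expect_error(read_ld_matrix(pm, pi), class = "targetmr_format_error")
  writeLines(c("1 0.5", "0.5 1"), pm)
  writeLines(c("rs1", "rs2", "rs3"), pi)
  expect_error(read_ld_matrix(pm, pi), class = "targetmr_format_error")

  # large asymmetry, off-unit diagonal, out-of-range entries all rejected
  m <- matrix(c(1, 0.2, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(validate_ld_matrix(m), class = "targetmr_format_error")
  m <- matrix(c(1.1, 0.2, 0.2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(validate_ld_matrix(m), class = "targetmr_format_error")
  m <- matrix(c(1, 1.2, 1.2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(validate_ld_matrix(m), class = "targetmr_format_error")

  # write/read round-trip
  set.seed(11)
  r <- rand_corr(5)
  dimnames(r) <- list(sprintf("v%d", 1:5), sprintf("v%d", 1:5))
  write_ld_matrix(r, pm, pi)
  writeLines(rownames(r), pi)
  expect_equal(read_ld_matrix(pm, pi), r, tolerance = 1e-12)
})

test_that("cis-region extraction uses closed 1-based intervals and sorts by position", {
  stats <- make_sumstats(sprintf("rs%d", 1:4),
                         c(1200001L, 799999L, 1200000L, 800000L),
                         "A", "G", beta = 0.1, se = 0.01)
  reg <- extract_cis_region(stats, "GENE1", 1000000L, 1000000L, window = 200000L)
  expect_identical(reg$pos, c(800000L, 1200000L))
  # order-invariance of input
  reg2 <- extract_cis_region(stats[sample(4), ], "GENE1", 1000000L, 1000000L)
  expect_identical(as.data.frame(reg), as.data.frame(reg2))
  # window 0 keeps the gene body only
  body <- extract_cis_region(stats, "GENE1", 800000L, 1200000L, window = 0L)
  expect_identical(body$pos, c(800000L, 1200000L))
  expect_identical(attr(reg, "window"), 200000L)
  expect_identical(formals(extract_cis_region)$window, 200000L)
})

test_that("harmonization aligns alleles, drops mismatches/palindromes, restricts LD", {
  exp <- make_sumstats(c("rs1", "rs2", "rs3", "rs4"), 1:4 * 1000L,
                       ea = c("A", "A", "A", "A"), oa = c("G", "G", "C", "T"),
                       beta = c(0.2, 0.3, 0.1, 0.2), se = 0.02)
  out <- make_sumstats(c("rs1", "rs2", "rs3", "rs4"), 1:4 * 1000L,
                       ea = c("G", "A", "A", "A"), oa = c("A", "G", "C", "T"),
                       beta = c(-0.05, 0.07, 0.02, 0.01), se = 0.01, eaf = 0.8)
  rho <- rand_corr(4)
  dimnames(rho) <- list(exp$variant_id, exp$variant_id)
  h <- harmonize(exp, out, rho)                       # rs4 is A/T palindromic
  expect_identical(h$variants$variant_id, c("rs1", "rs2", "rs3"))
  expect_equal(h$variants$b_y, c(0.05, 0.07, 0.02))   # rs1 flipped
  expect_identical(h$dropped$reason, "palindromic")
  expect_identical(rownames(h$rho), h$variants$variant_id)
  expect_equal(h$rho, rho[1:3, 1:3])

  h2 <- harmonize(exp, out, rho, drop_palindromic = FALSE)
  expect_identical(h2$variants$variant_id, c("rs1", "rs2", "rs3", "rs4"))

  # mismatching allele pair dropped with reason
  out$other_allele[3] <- "T"
  h3 <- harmonize(exp, out, rho)
  expect_true("allele mismatch" %in% h3$dropped$reason)
  expect_false("rs3" %in% h3$variants$variant_id)

  # no overlap is an explicit error
  out2 <- out
  out2$variant_id <- paste0("x", out2$variant_id)
  expect_error(harmonize(exp, out2, rho), "no overlapping",
               class = "targetmr_harmonize_error")
})

test_that("harmonization orientation is an involution", {
  exp <- make_sumstats(c("rs1", "rs2"), c(1000L, 2000L), c("A", "C"), c("G", "A"),
                       beta = c(0.2, -0.1), se = 0.02)
  out_fwd <- make_sumstats(c("rs1", "rs2"), c(1000L, 2000L), c("A", "C"), c("G", "A"),
                           beta = c(0.05, 0.01), se = 0.01, eaf = 0.3)
  # flip outcome alleles twice -> same harmonized betas as never flipping
  flip <- function(s) {
    s2 <- s
    s2$effect_allele <- s$other_allele
    s2$other_allele <- s$effect_allele
    s2$beta <- -s$beta
    s2$eaf <- 1 - s$eaf
    s2
  }
  h0 <- harmonize(exp, out_fwd)
  h1 <- harmonize(exp, flip(out_fwd))
  h2 <- harmonize(exp, flip(flip(out_fwd)))
  expect_equal(h1$variants$b_y, h0$variants$b_y)
  expect_equal(as.data.frame(h2$variants), as.data.frame(h0$variants))
})
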