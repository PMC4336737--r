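test_that("contig assignment applies the 97% and 50%-partial rules", {
  aln <- data.frame(
    contig_id = c("c1", "c2", "c3", "c4"),
    peptidase_id = "p1",
    identity = c(0.98, 0.98, 0.96, 0.98),
    aligned_fraction = c(1.0, 0.6, 1.0, 0.4))
  out <- assign_contigs(aln)
  expect_equal(out$contig_id, c("c1", "c2"))
  expect_equal(out$contribution_weight, c(1.0, 0.6))
  expect_error(assign_contigs(transform(aln, identity = 1.2)), "\\[0, 1\\]")
})

test_that("rpkm arithmetic is exact", {
  expect_equal(rpkm(1000, 1000, 1e6), 1000)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(250, 2000, 5e6), 25)
  expect_error(rpkm(10, 0, 1e6), "length")
  expect_error(rpkm(10, 100, 0), "total")
})

two_contig_setup <- function() {
  list(
    assignments = data.frame(
      contig_id = c("cA", "cB"), peptidase_id = c("A", "B"),
      identity = 1, aligned_fraction = 1, contribution_weight = 1),
    lengths = c(cA = 1000, cB = 1000))
}

test_that("naive counting gives one full unit at every map site", {
  s <- two_contig_setup()
  aln <- data.frame(
    read_id = c("r1", "r2", "r2", "r3"),
    contig_id = c("cA", "cA", "cB", "cB"))
  n <- count_naive(aln, s$assignments)
  expect_equal(n[["A"]], 2)   # r1 unique + r2 multiread full unit
  expect_equal(n[["B"]], 2)   # r2 + r3
  expect_equal(unname(count_naive(aln[0, ], s$assignments)), c(0, 0))
})

test_that("rescue splits multireads by unique-read density", {
  s <- two_contig_setup()
  # unique-read densities 1:3 -> multiread fractions 0.25 / 0.75
  aln <- rbind(
    data.frame(read_id = "u1", contig_id = "cA"),
    data.frame(read_id = paste0("v", 1:3), contig_id = "cB"),
    data.frame(read_id = "m", contig_id = c("cA", "cB")))
  r <- count_rescue(aln, s$assignments, s$lengths)
  expect_equal(r[["A"]], 1 + 0.25)
  expect_equal(r[["B"]], 3 + 0.75)
  # zero unique reads -> equal split
  aln0 <- data.frame(read_id = "m", contig_id = c("cA", "cB"))
  r0 <- count_rescue(aln0, s$assignments, s$lengths)
  expect_equal(unname(r0), c(0.5, 0.5))
})

test_that("rescue conserves reads: every multiread contributes one unit", {
  set.seed(19)
  contigs <- paste0("c", 1:6)
  lens <- setNames(sample(500:2000, 6), contigs)
  rows <- list()
  for (r in 1:400) {
    k <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
    rows[[r]] <- data.frame(read_id = paste0("r", r),
                            contig_id = sample(contigs, k))
  }
  aln <- do.call(rbind, rows)
  assignments <- data.frame(contig_id = contigs, peptidase_id = contigs,
                            identity = 1, aligned_fraction = 1,
                            contribution_weight = 1)
  res <- count_rescue(aln, assignments, lens)
  expect_equal(sum(res), length(unique(aln$read_id)), tolerance = 1e-9)
})

test_that("naive and rescue agree exactly when no multireads exist", {
  set.seed(23)
  contigs <- paste0("c", 1:4)
  aln <- data.frame(read_id = paste0("r", 1:200),
                    contig_id = sample(contigs, 200, replace = TRUE))
  assignments <- data.frame(contig_id = contigs, peptidase_id = contigs,
                            identity = 1, aligned_fraction = 1,
                            contribution_weight = 1)
  lens <- setNames(rep(1000, 4), contigs)
  expect_identical(count_naive(aln, assignments),
                   count_rescue(aln, assignments, lens))
})

test_that("relative percentages divide by the summed RPKM", {
  rec <- data.frame(peptidase_id = c("a", "b", "c"),
                    rpkm_naive = c(50, 30, 20))
  out <- relative_expression(rec)
  expect_equal(out$relative_pct_naive, c(50, 30, 20))
  one <- relative_expression(data.frame(peptidase_id = "a", rpkm_naive = 7))
  expect_equal(one$relative_pct_naive, 100)
  expect_error(relative_expression(data.frame(peptidase_id = "a",
                                              rpkm_naive = 0)), "zero")
})

test_that("relative percentages sum to 100 on the catalogue fixture, with
          the major cathepsin L holding the largest share", {
  fx <- read_catalogue_fixture("tm")
  rec <- data.frame(peptidase_id = fx$id, rpkm_naive = fx$rpkm,
                    rpkm_rescue = fx$rescue)
  out <- relative_expression(rec)
  expect_equal(sum(out$relative_pct_naive), 100, tolerance = 1e-9)
  expect_equal(sum(out$relative_pct_rescue), 100, tolerance = 1e-9)
  expect_equal(out$peptidase_id[which.max(out$relative_pct_naive)], "TmL13")
  expect_equal(out$peptidase_id[which.max(out$relative_pct_rescue)], "TmL13")
})

# two paralogs sharing an identical 5' region so a controlled fraction of
# reads multireads between them
paralog_pair <- function(shared_frac = 0.3, len = 1200) {
  shared <- paste(sample(c("A", "C", "G", "T"), shared_frac * len,
                         replace = TRUE), collapse = "")
  tail1 <- paste(sample(c("A", "C", "G", "T"), len - nchar(shared),
                        replace = TRUE), collapse = "")
  tail2 <- paste(sample(c("A", "C", "G", "T"), len - nchar(shared),
                        replace = TRUE), collapse = "")
  c(gA = paste0(shared, tail1), gB = paste0(shared, tail2))
}

test_that("rescue RPKM recovers the true expression ratio better than naive", {
  set.seed(29)
  errs <- matrix(NA_real_, 20, 2,
                 dimnames = list(NULL, c("naive", "rescue")))
  for (s in 1:20) {
    genes <- paralog_pair()
    truth <- c(gA = 100, gB = 300)
    rd <- simulate_reads(genes, truth, 3000, read_length = 60,
                         error_rate = 0, seed = s)
    aln <- map_reads_exact(rd$reads, genes)
    assignments <- data.frame(contig_id = names(genes),
                              peptidase_id = names(genes), identity = 1,
                              aligned_fraction = 1, contribution_weight = 1)
    lens <- nchar(genes)
    q <- quantify_expression(aln, assignments, lens, lens)
    true_pct <- truth / sum(truth) * 100
    errs[s, "naive"] <- mean(abs(q$relative_pct_naive - true_pct) / true_pct)
    errs[s, "rescue"] <- mean(abs(q$relative_pct_rescue - true_pct) / true_pct)
  }
  expect_lte(mean(errs[, "rescue"]), mean(errs[, "naive"]))
})
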