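toy_path <- function(which) {
  system.file("extdata", paste0("toy_", which, "_motifs_synthetic.tsv"),
              package = "kinetophos")
}

test_that("similarity weights down-weight redundant peptides", {
  expect_equal(peptide_weights(c("RVSF", "RVSF", "RVSF")), rep(1 / 3, 3))
  expect_equal(peptide_weights("RVSF"), 1)

  # hand-computed Henikoff weights on a 3 x 2 toy alignment:
  # col {A,A,C}: r=2, A gets 1/(2*2), C gets 1/(2*1); col {G,G,D} likewise;
  # raw weights (1/2, 1/2, 1) normalise to (1/4, 1/4, 1/2)
  expect_equal(peptide_weights(c("AG", "AG", "CD")), c(0.25, 0.25, 0.5))

  w <- peptide_weights(c("RVSF", "RVSF", "KVTF"))
  expect_gt(w[3], 1 / 3)
  expect_equal(sum(w), 1)

  expect_error(peptide_weights(c("RVSF", "RVS")), "same length")
})

test_that("PSSM scores are background log-odds with pseudocount smoothing", {
  peps <- c("RVSF", "KVTF", "RVQF")
  # huge pseudocount: pure background, scores vanish
  p_inf <- build_pssm(peps, alpha = 1e9)
  expect_lt(max(abs(p_inf$matrix)), 1e-5)

  # invariant column, uniform background, no pseudocount: closed-form log-odds
  p0 <- build_pssm("RVSF", background = uniform_background(), alpha = 0)
  expect_equal(unname(p0$matrix[1, "R"]), log(1 / 0.05))
  expect_true(is.infinite(p0$matrix[1, "A"]) && p0$matrix[1, "A"] < 0)
  # the default pseudocount guards the -Inf
  p1 <- build_pssm("RVSF", background = uniform_background(), alpha = 1)
  expect_true(all(is.finite(p1$matrix)))

  # peptide order is irrelevant
  expect_equal(build_pssm(peps)$matrix, build_pssm(rev(peps))$matrix)

  expect_error(build_pssm(peps, background = c(A = 1)), "20 amino acids")
})

test_that("duplicate-peptide inflation is damped by similarity weights", {
  peps <- c("RVSFAE", "KVTFID", "RVQFGN", "HVSFPE", "KVAFDQ")
  base <- build_pssm(peps)
  infl <- build_pssm(c(peps, peps[1]))
  # the duplicated peptide splits its Henikoff weight with its copy, so the
  # weighted frequency shift is strictly smaller than the unweighted one
  base_u <- build_pssm(peps, weights = rep(1 / 5, 5))
  infl_u <- build_pssm(c(peps, peps[1]), weights = rep(1 / 6, 6))
  d_w <- max(abs(base$freqs - infl$freqs))
  d_u <- max(abs(base_u$freqs - infl_u$freqs))
  expect_lt(d_w, d_u)
  expect_lt(d_w, 0.08)
  # scores also feel the pseudocount blend n-dependence on zero-count cells,
  # which bounds the total shift at well under one log unit here
  expect_lt(max(abs(base$matrix - infl$matrix)), 0.4)
})

test_that("binomial enrichment equals exact pmf summation", {
  for (n in c(5L, 17L, 50L)) {
    for (p in c(0.05, 0.3, 0.5)) {
      for (k in 0:n) {
        brute <- sum(stats::dbinom(k:n, n, p))
        expect_lt(abs(binomial_enrichment(k, n, p) - brute), 1e-12)
      }
    }
  }
  expect_equal(binomial_enrichment(0, 10, 0.3), 1)
  expect_equal(binomial_enrichment(10, 10, 1), 1)
  expect_equal(binomial_enrichment(3, 10, 0.3, convention = "pmf"),
               stats::dbinom(3, 10, 0.3))
  # numerically sane at large n, monotone decreasing in k through the bulk
  x <- binomial_enrichment(c(4900, 5000, 5100), 1e4, 0.5)
  expect_true(all(is.finite(x) & x >= 0 & x <= 1))
  expect_true(all(diff(x) < 0))
  expect_error(binomial_enrichment(2, 10, 1.5), "p must be")
  expect_error(binomial_enrichment(11, 10, 0.5), "k <= n")
})

test_that("logo values vanish at background and peak on invariant columns", {
  # one of each residue: every count k = 1 = n*p under the uniform background
  peps <- paste0(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                   "R","S","T","V","W","Y"), "V")
  lg <- logo_matrix(peps, background = uniform_background())
  expect_lt(max(abs(lg$values[1, ])), 0.1)
  # the invariant second column peaks at V with the exact closed form
  expect_equal(unname(lg$values[2, "V"]), -20 * log10(0.05))
  expect_true(all(lg$values[2, setdiff(colnames(lg$values), "V")] <
                    lg$values[2, "V"]))
})

test_that("group enrichment is starred at the published thresholds", {
  expect_identical(enrichment_stars(c(0.5, 0.005, 5e-4, 5e-5)),
                   c("", "*", "**", "***"))
  peps <- c("SSSS", "STSS", "TSST", "SSTS")  # all-ST alignment
  lg <- logo_matrix(peps, background = uniform_background())
  st <- lg$enrichment[lg$enrichment$target == "ST", ]
  expect_equal(st$k, rep(4L, 4))
  expect_equal(st$probability, rep(0.1^4, 4), tolerance = 1e-12)
  expect_identical(st$stars, rep("**", 4))
})

test_that("kinase-class annotation follows the consensus patterns in order", {
  expect_identical(classify_kinase_site("RAS", 3), "basophilic")
  expect_identical(classify_kinase_site("KAAS", 4), "basophilic")  # [KR]xxS
  expect_identical(classify_kinase_site("DGT", 3), "acidophilic")
  expect_identical(classify_kinase_site("ASP", 2), "proline_directed")
  expect_identical(classify_kinase_site("GGS", 3), "other")
  # multiple matches: all labels, primary first (printed pattern order)
  expect_identical(classify_kinase_site("DASP", 3),
                   c("acidophilic", "proline_directed"))
  expect_identical(classify_kinase_site("RASP", 3),
                   c("basophilic", "proline_directed"))
  # basophilic pattern is serine-specific; threonine falls through
  expect_identical(classify_kinase_site("RAT", 3), "other")
  expect_error(classify_kinase_site("RAS", 9), "out of range")
  expect_error(classify_kinase_site("RAV", 3), "must be S or T")
})

test_that("phospho summaries count validated and potential sites per motif", {
  rv <- read_motif_table(toy_path("rvxf"))
  expect_s3_class(rv, "kp_motifs")
  s <- phospho_summary(rv)
  expect_equal(unname(s["phosphorylated"]), 2 / 8)    # hand count
  expect_equal(unname(s["phosphorylatable"]), 4 / 8)  # hand count

  lx <- read_motif_table(toy_path("lxxixe"))
  s2 <- phospho_summary(lx)
  expect_equal(unname(s2["phosphorylated"]), 2 / 6)
  expect_equal(unname(s2["phosphorylatable"]), 1.0)

  # a validated site implies an S/T, so the inequality is structural
  expect_lte(s["phosphorylated"], s["phosphorylatable"])
  expect_lte(s2["phosphorylated"], s2["phosphorylatable"])

  # no S/T in the region: both fractions vanish
  none <- rv[4:6, ]
  class(none) <- class(rv)
  expect_equal(unname(phospho_summary(none)), c(0, 0))

  expect_error(phospho_summary(rv[0, ]), "empty")
  expect_error(phospho_summary(rv, region = 1:40), "outside")
})

test_that("motif tables are validated on read", {
  bad <- tempfile(fileext = ".tsv")
  on.exit(unlink(bad))
  writeLines(c("protein_id\tpeptide\tclass\tphosphosites\tsource",
               "X1\tKKRVAFAE\tRVxF\t5\tvalidated"), bad)  # site on A
  expect_error(read_motif_table(bad), "non-phosphorylatable")
  writeLines(c("protein_id\tpeptide\tclass\tphosphosites\tsource",
               "X1\tKKRVSFAE\tRVxF\t55\tvalidated"), bad)
  expect_error(read_motif_table(bad), "outside the motif frame")
})

test_that("the shipped disordered-region background is a distribution", {
  bg <- disordered_background()
  expect_equal(sum(bg), 1)
  expect_length(bg, 20)
  expect_gt(bg[["P"]], bg[["W"]])   # disorder favours P over W
  expect_equal(sum(uniform_background()), 1)
})
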