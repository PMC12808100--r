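test_that("scan_consensus finds the worked peptide motifs", {
  # a DONSON-derived peptide: one NPF at 8-10
  hits <- scan_consensus("GPAAARRNPFARLDNRPR", "NPF")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 8L)
  expect_equal(hits$end, 10L)
  expect_identical(hits$matched_sequence, "NPF")
  # 5 flanking residues each side, truncated at the N-terminus
  expect_identical(hits$context, "AAARRNPFARLDN")
  # a SYNJ1-derived fragment carrying three NPF motifs
  hits3 <- scan_consensus("RSSPNPFITGLTRTNPFSDRTAAPGNPFRAKS", "NPF")
  expect_equal(nrow(hits3), 3)
  # all-false mask suppresses everything
  sq <- "GPAAARRNPFARLDNRPR"
  expect_equal(
    nrow(scan_consensus(sq, "NPF", mask = rep(FALSE, nchar(sq)))), 0
  )
  expect_error(scan_consensus(sq, "NP1"), "invalid pattern")
})

test_that("scan_consensus equals the naive sliding-window oracle", {
  set.seed(17)
  patterns <- c("NPF", "NPxY", "DPF", "LxxLL")
  for (i in 1:20) {
    sq <- random_aa(sample(30:120, 1))
    for (pat in patterns) {
      got <- scan_consensus(sq, pat)$start
      want <- oracle_scan_positions(sq, pat)
      expect_identical(as.integer(got), as.integer(want))
    }
  }
  # overlapping matches are all reported
  expect_equal(scan_consensus("AAAA", "AA")$start, 1:3)
})

test_that("disorder_mask combines domains, experiment and predictors", {
  n <- 30
  # all residues inside one domain -> empty mask
  m <- disorder_mask(strrep("A", n),
    tracks = list(iupred = rep(0.9, n)),
    domains = cbind(1, n))
  expect_false(any(m))
  # iupred 0.41 kept vs 0.39 dropped (threshold is strict >0.4)
  iup <- c(rep(0.41, 10), rep(0.39, 10), rep(0.41, 10))
  m2 <- disorder_mask(strrep("A", n), tracks = list(iupred = iup))
  expect_true(all(m2[1:10]))
  expect_false(any(m2[11:20]))
  # a 4-residue run flanked by order is cleared
  iup3 <- rep(0.1, n)
  iup3[10:13] <- 0.9
  m3 <- disorder_mask(strrep("A", n), tracks = list(iupred = iup3))
  expect_false(any(m3))
  iup3[10:14] <- 0.9 # 5 residues survive
  m4 <- disorder_mask(strrep("A", n), tracks = list(iupred = iup3))
  expect_true(all(m4[10:14]))
  # when an AF2-rsa track exists, iupred is not consulted by default
  m5 <- disorder_mask(strrep("A", n),
    tracks = list(af2_rsa = rep(0.1, n), iupred = rep(0.9, n)))
  expect_false(any(m5))
  m6 <- disorder_mask(strrep("A", n),
    tracks = list(af2_rsa = rep(0.1, n), iupred = rep(0.9, n)),
    combine = "or")
  expect_true(all(m6))
  # experimental disorder always counts
  m7 <- disorder_mask(strrep("A", n),
    tracks = list(disorder_experimental = rep(1, n),
      af2_rsa = rep(0.1, n)))
  expect_true(all(m7))
  expect_error(
    disorder_mask("AAA", tracks = list(iupred = rep(0.5, 5))),
    "length"
  )
})

test_that("disorder_mask is monotone in the IUPred threshold", {
  set.seed(23)
  iup <- runif(200)
  sq <- strrep("A", 200)
  lo <- disorder_mask(sq, list(iupred = iup), iupred_threshold = 0.3)
  hi <- disorder_mask(sq, list(iupred = iup), iupred_threshold = 0.6)
  expect_true(all(lo[hi])) # raising the cutoff never adds residues
})

test_that("motif_enrichment reproduces the interactome arithmetic", {
  enr <- motif_enrichment(17, 70, 446, 20000)
  expect_equal(enr$expected, 70 * 446 / 20000, tolerance = 1e-12)
  expect_equal(enr$expected, 1.561, tolerance = 1e-3)
  expect_gt(enr$fold, 10)
  expect_equal(enr$fold, 10.89, tolerance = 1e-3)
  expect_lt(enr$p, 1e-10)
  expect_equal(motif_enrichment(0, 70, 446, 20000)$fold, 0)
  expect_error(motif_enrichment(1, 5, 3, 0), "proteome_size")
  # fold is scale-invariant in all four counts
  base <- motif_enrichment(3, 10, 40, 200)$fold
  expect_equal(motif_enrichment(9, 30, 120, 600)$fold, base)
})

test_that("hypergeometric p equals exhaustive enumeration for N <= 20", {
  for (N in c(10, 15, 20)) {
    for (K in c(2, 5, N %/% 2)) {
      for (n in c(3, 6)) {
        for (k in 0:min(K, n)) {
          got <- motif_enrichment(k, n, K, N)$p
          want <- oracle_hyper_upper(k, K, N, n)
          expect_equal(got, want, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("conservation scoring averages the core only", {
  expect_equal(score_instance_conservation(4, 6, rep(0.7, 10)), 0.7)
  cons <- c(0, 0, 0, 0.9, 0.6, 0.9, 0, 0, 0, 0)
  expect_equal(score_instance_conservation(4, 6, cons), 0.8)
  # flank values cannot affect the score
  cons2 <- cons
  cons2[c(1:3, 7:10)] <- 1
  expect_equal(
    score_instance_conservation(4, 6, cons2),
    score_instance_conservation(4, 6, cons)
  )
  expect_error(score_instance_conservation(8, 12, cons), "cover")
  expect_error(score_instance_conservation(4, 6, c(0, 0, 0, NA, 1, 1, 0)),
    "missing")
})

test_that("rank_motif_types orders by mean conservation with lexical ties", {
  inst <- data.frame(
    motif_type = c("AAA", "AAA", "BBB"),
    conservation = c(0.9, 0.7, 0.85)
  )
  rk <- rank_motif_types(inst)
  expect_identical(rk$motif_type, c("BBB", "AAA"))
  expect_identical(rk$rank, 1:2)
  expect_equal(rk$mean_conservation, c(0.85, 0.8))
  expect_identical(rk$instance_count, c(1L, 2L))
  # deterministic lexicographic tie-break
  tie <- data.frame(motif_type = c("ZZZ", "MMM"), conservation = c(0.5, 0.5))
  expect_identical(rank_motif_types(tie)$motif_type, c("MMM", "ZZZ"))
  # permutation invariance
  set.seed(2)
  inst2 <- data.frame(
    motif_type = sample(LETTERS[1:5], 30, replace = TRUE),
    conservation = runif(30)
  )
  rk1 <- rank_motif_types(inst2)
  rk2 <- rank_motif_types(inst2[sample(nrow(inst2)), ])
  expect_identical(rk1, rk2)
  expect_equal(nrow(rank_motif_types(inst2[0, ])), 0)
  expect_identical(rank_motif_types(data.frame(
    motif_type = "NPF", conservation = 0.9))$rank, 1L)
})

test_that("conservation re-ranking recovers the planted type", {
  first <- vapply(1:100, function(i) {
    sim <- simulate_motif_dataset(seed = i)
    inst <- sim$instances
    inst$conservation <- mapply(
      function(id, s, e) {
        score_instance_conservation(s, e, sim$tracks[[id]]$conservation)
      },
      inst$protein_id, inst$start, inst$end
    )
    rk <- rank_motif_types(inst)
    rk$motif_type[1] == sim$planted_consensus
  }, logical(1))
  expect_gte(mean(first), 0.95)
})

test_that("a null conservation effect gives no systematic top rank", {
  ranks <- vapply(1:30, function(i) {
    sim <- simulate_motif_dataset(seed = 1000 + i, conservation_effect = 0)
    inst <- sim$instances
    inst$conservation <- mapply(
      function(id, s, e) {
        score_instance_conservation(s, e, sim$tracks[[id]]$conservation)
      },
      inst$protein_id, inst$start, inst$end
    )
    rk <- rank_motif_types(inst)
    which(rk$motif_type == sim$planted_consensus)
  }, integer(1))
  expect_lt(mean(ranks == 1), 0.5)
  expect_gt(length(unique(ranks)), 3)
})

test_that("planted instances are recovered by scan_consensus in disorder", {
  sim <- simulate_motif_dataset(seed = 4)
  planted <- sim$instances[sim$instances$is_planted, ]
  found <- character(0)
  for (id in unique(planted$protein_id)) {
    dom <- sim$domains[sim$domains$protein_id == id, c("start", "end")]
    mask <- disorder_mask(sim$sequences[[id]], sim$tracks[[id]], dom)
    h <- scan_consensus(sim$sequences[[id]], sim$planted_consensus,
      mask = mask, protein_id = id)
    found <- c(found, paste(h$protein_id, h$start))
  }
  expect_true(all(paste(planted$protein_id, planted$start) %in% found))
})
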