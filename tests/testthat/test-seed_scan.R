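# miRNA with a non-degenerate seed used throughout; seed core (positions
# 2-7) is ACGAUC, so the target core match is GATCGT
MIR <- "UACGAUCGAAGCUGCCAUGGAU"

test_that("circularize appends probe_len - 1 leading bases", {
  expect_equal(circularize("ACGT", 3), "ACGTAC")
  expect_equal(circularize("ACGT", 1), "ACGT")
  expect_error(circularize("ACGT", 5), "probe_len")
  expect_error(circularize("ACGT", 0), "probe_len")
})

test_that("targets without the seed hexamer yield no sites", {
  expect_equal(nrow(find_seed_sites(strrep("A", 50), MIR)), 0L)
  expect_error(find_seed_sites("ACGTACGT", "ACGUACG"), "at least 8")
})

test_that("site classes follow the canonical hierarchy", {
  core <- "GATCGT"      # matches miRNA positions 2-7
  m8 <- "C"             # complement of miRNA position 8 (G)
  pad <- strrep("T", 20)
  # 8mer: m8 match + A opposite position 1
  s8 <- find_seed_sites(paste0(pad, m8, core, "A", pad), MIR)
  expect_equal(s8$site_class, "8mer")
  expect_equal(s8$position, 20L)
  expect_false(s8$spans_junction)
  # 7mer-m8: m8 match, no A
  s7m8 <- find_seed_sites(paste0(pad, m8, core, "G", pad), MIR)
  expect_equal(s7m8$site_class, "7mer-m8")
  expect_equal(s7m8$position, 20L)
  # 7mer-A1: A, no m8 match
  s7a1 <- find_seed_sites(paste0(pad, "G", core, "A", pad), MIR)
  expect_equal(s7a1$site_class, "7mer-A1")
  expect_equal(s7a1$position, 21L)
  # 6mer: neither
  s6 <- find_seed_sites(paste0(pad, "G", core, "G", pad), MIR)
  expect_equal(s6$site_class, "6mer")
  expect_equal(s6$position, 21L)
})

test_that("junction-spanning sites are found once at the modular position", {
  core <- "GATCGT"; m8 <- "C"
  L <- 40
  # plant a 7mer-m8 occupying the last 4 nt and first 3 nt of the circle
  site <- paste0(m8, core)  # 7 nt
  seq <- paste0(substr(site, 5, 7), strrep("T", L - 7), substr(site, 1, 4))
  hits <- find_seed_sites(seq, MIR)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, L - 4L)
  expect_true(hits$spans_junction)
  expect_equal(hits$site_class, "7mer-m8")
})

test_that("scanning agrees with the doubled-sequence brute-force oracle", {
  set.seed(51)
  for (i in 1:60) {
    s <- random_dna(sample(25:60, 1))
    got <- find_seed_sites(s, MIR)
    want <- seed_sites_oracle(s, MIR)
    expect_equal(got[, c("position", "site_class")], want, ignore_attr = TRUE)
  }
})

test_that("site sets are rotation equivariant", {
  set.seed(52)
  for (i in 1:20) {
    s <- random_dna(30)
    base <- find_seed_sites(s, MIR)
    for (r in 1:29) {
      rot <- paste0(substr(s, r + 1, 30), substr(s, 1, r))
      hits <- find_seed_sites(rot, MIR)
      expect_setequal(paste((hits$position + r) %% 30, hits$site_class),
                      paste(base$position, base$site_class))
    }
  }
})

test_that("planted seed sites are recovered exactly from the ledger", {
  d <- tiny_dataset()
  circ_seqs <- read_fasta(d$paths$circ_fasta)
  mirna_seqs <- read_fasta(d$paths$mirna_fasta)
  got <- scan_seed_sites(circ_seqs, mirna_seqs)
  planted <- d$ledger$planted_seed_sites
  expect_gt(nrow(planted), 0L)
  expect_true(any(planted$spans_junction))
  expect_frame_equal(got, planted,
                     c("circ_id", "mirna_id", "position", "site_class",
                       "spans_junction"))
})

test_that("conserved site counting uses the alignment map and tolerance", {
  d <- tiny_dataset()
  circ_seqs <- read_fasta(d$paths$circ_fasta)
  spB <- read_fasta(d$paths$orth_fasta_spB)
  mirna <- read_fasta(d$paths$mirna_fasta)[["synmiR-1"]]
  orth <- read_orthologs(d$paths$orthologs)
  id <- d$ledger$planted_candidate_ids[1]
  idB <- orth$spB_id[match(id, orth$spA_id)]
  seqs <- c(a = circ_seqs[[id]], b = spB[[idB]], c = circ_seqs[[id]])
  sites <- lapply(seqs, find_seed_sites, mirna_seq = mirna, mirna_id = "synmiR-1")
  expect_equal(count_conserved_sites(sites, seqs), 3L)
  # drop one site in one species: only the remaining sites are conserved
  sites_drop <- sites
  sites_drop$b <- sites_drop$b[-1, ]
  expect_equal(count_conserved_sites(sites_drop, seqs), 2L)
  # a species with no strong sites leaves nothing conserved
  sites_none <- sites
  sites_none$c <- sites_none$c[0, ]
  expect_equal(count_conserved_sites(sites_none, seqs), 0L)
})

test_that("PWM scanning scores log-odds on both strands", {
  pwm <- matrix(0.01 / 3, nrow = 4, ncol = 5,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  consensus <- c("T", "G", "A", "C", "C")
  for (j in 1:5) pwm[consensus[j], j] <- 0.99
  seq <- paste0(strrep("A", 17), paste(consensus, collapse = ""), strrep("A", 10))
  hits <- scan_pwm(seq, pwm, threshold_bits = 5)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$position, 17L)
  # oracle: independent per-column log-odds sum at the planted position
  p <- sweep(pwm + 0.01, 2, colSums(pwm + 0.01), "/")
  expected <- sum(log2(vapply(1:5, function(j) p[consensus[j], j], numeric(1)) / 0.25))
  expect_equal(fwd$score, expected, tolerance = 1e-12)
  # nothing above an unattainable threshold
  expect_equal(nrow(scan_pwm(seq, pwm, threshold_bits = expected + 1)), 0L)
  # uniform PWM scores 0 bits everywhere
  unif <- matrix(0.25, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  all0 <- scan_pwm("ACGTACGTACGT", unif, threshold_bits = -1)
  expect_true(all(abs(all0$score) < 1e-12))
  expect_equal(nrow(all0), 2 * (12 - 5 + 1))
  expect_error(scan_pwm(seq, pwm * 2, 1), "sum to 1")
})

test_that("palindromic PWMs score both strands identically", {
  pwm <- matrix(0.05 / 3, nrow = 4, ncol = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(c("G", "A", "T", "C"))) pwm[c("G", "A", "T", "C")[j], j] <- 0.95
  set.seed(53)
  s <- random_dna(40)
  hits <- scan_pwm(s, pwm, threshold_bits = -Inf)
  fwd <- hits[hits$strand == "+", ]
  rev <- hits[hits$strand == "-", ]
  expect_equal(fwd$score[order(fwd$position)], rev$score[order(rev$position)],
               tolerance = 1e-12)
})
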