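# Tiling, self-affinity filtering, hit search, classification and
# probeset assembly.

test_that("tiling emits the expected candidate grid", {
  set.seed(301)
  region <- random_dna(100)
  expect_equal(nrow(tile_region(region, "r", step = 1)), 76L)
  t4 <- tile_region(region, "r", step = 4)
  expect_equal(nrow(t4), 19L)
  expect_equal(t4$start, seq(0L, 72L, by = 4L))
  expect_equal(t4$end - t4$start, rep(25L, 19L))
  expect_warning(short <- tile_region(random_dna(24), "s"), "shorter")
  expect_equal(nrow(short), 0L)
  # masked bases are skipped
  masked <- paste0(substr(region, 1, 30), "N", substr(region, 32, 100))
  tm <- tile_region(masked, "m", step = 1)
  expect_false(any(tm$start <= 30 & tm$end > 30))
  # both orientations double the candidates with reverse complements
  t2 <- tile_region(region, "r", step = 4, orientations = 2)
  expect_equal(nrow(t2), 38L)
  anti <- t2[t2$orientation == "antisense", ]
  sense <- t2[t2$orientation == "sense", ]
  expect_equal(anti$sequence, revcomp(sense$sequence))
})

test_that("self-affinity filter keeps the boundary case and needs a threshold", {
  set.seed(302)
  m <- flat_model()  # PM self-affinity of any 25-mer is exactly 21
  cand <- tile_region(random_dna(60), "r", step = 4)
  expect_error(self_affinity_filter(cand, m), "not calibrated")
  f_eq <- self_affinity_filter(cand, set_threshold(m, 21))
  expect_true(all(f_eq$status == "candidate"))  # boundary inclusive
  expect_true(all(f_eq$self_affinity == 21))
  f_above <- self_affinity_filter(cand, set_threshold(m, 21.5))
  expect_true(all(f_above$status == "rejected_low_affinity"))
  f_excl <- self_affinity_filter(cand, set_threshold(m, 21),
                                 inclusive = FALSE)
  expect_true(all(f_excl$status == "rejected_low_affinity"))
  expect_equal(nrow(self_affinity_filter(cand[0, ], set_threshold(m, 21))),
               0L)
})

test_that("hit search finds the self-hit and planted paralogs within budget", {
  set.seed(303)
  lib <- c(src = random_dna(300))
  probe <- substr(lib[["src"]], 101, 125)
  hits <- find_hits(probe, lib, max_mm = 3, max_gaps = 1)
  expect_true(any(hits$position == 100 & hits$n_mm == 0))
  # planted paralog with 2 substitutions: found iff max_mm >= 2
  paralog <- plant_substitutions(probe, c(5, 19))
  lib2 <- c(lib, par = paste0(random_dna(50), paralog, random_dna(50)))
  h2 <- find_hits(probe, lib2, max_mm = 2, max_gaps = 0)
  expect_true(any(h2$target_id == "par" & h2$position == 50 & h2$n_mm == 2))
  h1 <- find_hits(probe, lib2, max_mm = 1, max_gaps = 0)
  expect_false(any(h1$target_id == "par"))
  # a probe matching nothing errors
  expect_error(find_hits(strrep("ACGTA", 5), lib, max_mm = 0, max_gaps = 0),
               "does not match")
})

test_that("identical hits across libraries merge into one", {
  set.seed(304)
  ref <- c(shared = random_dna(120))
  probe <- substr(ref[["shared"]], 21, 45)
  hits <- find_hits(probe, list(ref, ref), max_mm = 1, max_gaps = 0)
  expect_equal(sum(hits$target_id == "shared" & hits$position == 20), 1L)
})

test_that("built-in hit search is complete against the exhaustive scan", {
  set.seed(305)
  for (rep in 1:30) {
    target <- random_dna(120)
    s0 <- sample(0:(120 - 25), 1)
    probe <- substr(target, s0 + 1, s0 + 25)
    # plant a variant of the probe elsewhere
    n_mm <- sample(0:3, 1)
    variant <- plant_substitutions(probe, sample(25, n_mm))
    if (runif(1) < 0.3) {
      pos <- sample(24, 1)
      variant <- paste0(substr(variant, 1, pos - 1),
                        substr(variant, pos + 1, nchar(variant)))
    }
    target2 <- paste0(target, random_dna(10), variant, random_dna(10))
    got <- find_hits(probe, c(t = target2), max_mm = 3, max_gaps = 1)
    want <- oracle_scan_hits(probe, target2, max_mm = 3, max_gaps = 1)
    # every oracle site is recovered: some search hit overlaps it at the
    # same or lower cost (the search clusters same-site alignments)
    for (r in seq_len(nrow(want))) {
      near <- got[abs(got$position - want$position[r]) <= 12L, ,
                  drop = FALSE]
      expect_gte(nrow(near), 1L)
      expect_lte(min(near$cost), want$cost[r] + 1e-9)
    }
  }
})

test_that("probe classification follows the hit-count rule", {
  set.seed(306)
  m <- set_threshold(flat_model(), 12)
  # flat model: PM hit scores 21, 1-MM hit 13.5, 2-MM (spread) hit well
  # below 12; build libraries with controlled numbers of good paralogs
  probe <- random_dna(25)
  embed <- function(seqs) {
    stats::setNames(vapply(seqs, function(s)
      paste0(random_dna(30), s, random_dna(30)), character(1)),
      sprintf("L%02d", seq_along(seqs)))
  }
  one_mm <- function(x) plant_substitutions(x, sample(25, 1))
  far_mm <- function(x) plant_substitutions(x, c(3, 22))
  lib1 <- embed(list(probe))
  c1 <- classify_probe(find_hits(probe, lib1, max_mm = 3,
                                 max_gaps = 1), m, self_target = "L01")
  expect_equal(c1$status, "specific")
  lib3 <- embed(list(probe, one_mm(probe), one_mm(probe)))
  c3 <- classify_probe(find_hits(probe, lib3, max_mm = 3,
                                 max_gaps = 1), m, self_target = "L01")
  expect_equal(c3$status, "potentially_cross_hybridizing")
  expect_equal(c3$n_above, 3L)
  expect_setequal(c3$partner_loci, c("L02", "L03"))
  lib4 <- embed(list(probe, one_mm(probe), one_mm(probe), one_mm(probe)))
  c4 <- classify_probe(find_hits(probe, lib4, max_mm = 3,
                                 max_gaps = 1), m, self_target = "L01")
  expect_equal(c4$status, "non_specific")
  # a diverged paralog (2 spread MMs) does not count as a hit above T
  lib_far <- embed(list(probe, far_mm(probe)))
  cf <- classify_probe(find_hits(probe, lib_far,
                                 max_mm = 3, max_gaps = 1), m,
                       self_target = "L01")
  expect_equal(cf$status, "specific")
})

test_that("lowering the threshold never makes a probe more specific", {
  set.seed(307)
  probe <- random_dna(25)
  libs <- stats::setNames(vapply(1:5, function(i)
    paste0(random_dna(20),
           plant_substitutions(probe, sample(25, sample(0:1, 1))),
           random_dna(20)), character(1)), paste0("L", 1:5))
  hits <- find_hits(probe, libs, max_mm = 3, max_gaps = 1)
  rank_of <- c(specific = 1, potentially_cross_hybridizing = 2,
               non_specific = 3)
  m <- flat_model()
  prev <- NULL
  for (T in c(20, 15, 12, 8, 2)) {  # decreasing thresholds
    st <- classify_probe(hits, set_threshold(m, T))$status
    if (!is.null(prev)) expect_gte(rank_of[[st]], rank_of[[prev]])
    prev <- st
  }
})

test_that("probeset assembly traces the greedy admission rules", {
  mk <- function(starts, status, aff = 21, partners = NULL) {
    n <- length(starts)
    df <- data.frame(probe_id = sprintf("p%02d", seq_len(n)),
                     start = starts, end = starts + 25L,
                     self_affinity = rep_len(aff, n),
                     status = rep_len(status, n),
                     stringsAsFactors = FALSE)
    df$partner_loci <- if (is.null(partners))
      replicate(n, character(0), simplify = FALSE) else partners
    df
  }
  # 10 specific candidates spaced 20 nt apart -> one probeset capped at 6
  ps <- assemble_probesets(mk(seq(0, 180, by = 20), "specific"), "locus")
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$n_probes, 6L)
  members <- attr(ps, "members")[[1]]
  expect_equal(members$probe_id, sprintf("p%02d", 1:6))  # ties -> leftmost
  # two passing probes 7 nt apart: only one kept
  ps2 <- assemble_probesets(mk(c(0, 7, 40, 80), "specific"), "locus")
  expect_equal(ps2$n_probes, 3L)
  expect_false("p02" %in% strsplit(ps2$probe_ids, ";")[[1]])
  # the closer competitor with higher affinity displaces its neighbor
  cand3 <- mk(c(0, 7, 40, 80), "specific",
              aff = c(10, 12, 10, 10))
  ps3 <- assemble_probesets(cand3, "locus")
  expect_true("p02" %in% strsplit(ps3$probe_ids, ";")[[1]])
  expect_false("p01" %in% strsplit(ps3$probe_ids, ";")[[1]])
  # no specific probe -> no probeset
  ps4 <- assemble_probesets(mk(c(0, 40, 80, 120),
                               "potentially_cross_hybridizing",
                               partners = list("x1", "x2", "x3", "x4")),
                            "locus")
  expect_equal(nrow(ps4), 0L)
  # shared cross-hybridization partner: second probe not admitted
  cand5 <- mk(c(0, 40, 80, 120),
              c("specific", "potentially_cross_hybridizing",
                "potentially_cross_hybridizing", "specific"),
              partners = list(character(0), "locusX", "locusX",
                              character(0)))
  ps5 <- assemble_probesets(cand5, "locus")
  expect_equal(ps5$n_probes, 3L)
  got <- strsplit(ps5$probe_ids, ";")[[1]]
  expect_length(intersect(c("p02", "p03"), got), 1L)
})

test_that("emitted probesets always satisfy the structural invariants", {
  set.seed(308)
  m <- set_threshold(flat_model(), 12)
  for (div in c(0.08, 0.15)) {
    fam <- simulate_family(3, length = 220, divergence = div,
                           seed = 400 + round(100 * div))
    res <- suppressMessages(
      design_probes(fam, list(fam), m, step = 4, max_mm = 3, max_gaps = 1))
    if (nrow(res$probesets) == 0L) next
    for (ps_id in res$probesets$probeset_id) {
      mem <- attr(res$probesets, "members")[[ps_id]]
      expect_true(isTRUE(probeset_ok(mem)))
      expect_gte(nrow(mem), 3L)
      expect_lte(nrow(mem), 6L)
      expect_lte(max(mem$end) - min(mem$start), 400L)
      if (nrow(mem) > 1L) {
        expect_gte(min(diff(sort(mem$start))), 8L)
      }
      expect_gte(sum(mem$status == "specific"), 1L)
    }
  }
})

test_that("identical loci (zero divergence) yield no probesets at all", {
  set.seed(309)
  m <- set_threshold(flat_model(), 12)
  fam <- simulate_family(4, length = 120, divergence = 0, seed = 41)
  res <- suppressMessages(
    design_probes(fam, list(fam), m, step = 4, max_mm = 3, max_gaps = 1))
  expect_equal(nrow(res$probesets), 0L)
  designed <- res$probes[res$probes$status != "rejected_low_affinity", ]
  expect_true(all(designed$status == "non_specific"))
})

test_that("the design pipeline is deterministic", {
  set.seed(310)
  m <- set_threshold(flat_model(), 12)
  fam <- simulate_family(2, length = 150, divergence = 0.12, seed = 42)
  r1 <- suppressMessages(design_probes(fam, list(fam), m, step = 4))
  r2 <- suppressMessages(design_probes(fam, list(fam), m, step = 4))
  expect_identical(r1$probes, r2$probes)
  expect_identical(r1$probesets, r2$probesets)
})
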