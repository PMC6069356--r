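test_that("enumeration matches hand counts and the independent interval counter", {
  m <- energy_model()
  # no Watson-Crick pairs at all
  expect_length(enumerate_structures("AAAA", m), 1L)
  # pairs exist but the hairpin minimum excludes them
  expect_length(enumerate_structures("GCGC", m), 1L)
  for (s in c("GGGAAACCC", "GCGCAAAGCGC", "ATATATATAT")) {
    expect_equal(length(enumerate_structures(s, m)), oracle_structure_count(s),
                 info = s)
  }
  set.seed(41)
  for (r in 1:10) {
    s <- random_seq(sample(8:14, 1))
    expect_equal(length(enumerate_structures(s, m)), oracle_structure_count(s),
                 info = s)
  }
  expect_error(enumerate_structures(strrep("A", 23), m), "guard")
})

test_that("DP partition function equals the enumeration oracle", {
  m <- energy_model()
  expect_equal(partition_function("AAAA", m), 1.0)
  set.seed(43)
  for (r in 1:20) {
    s <- random_seq(sample(8:16, 1))
    en <- enumeration_partition_function(s, m)
    expect_equal(partition_function(s, m), en$Q, tolerance = 1e-11, info = s)
  }
  # Q depends on bases and model only, not the strand name
  expect_identical(partition_function(dna_strand("a", "GGGAAACCC"), m),
                   partition_function(dna_strand("b", "GGGAAACCC"), m))
})

test_that("structure probabilities normalize and obey the Boltzmann ratio law", {
  m <- energy_model()
  empty <- secondary_structure("AAAA")
  expect_equal(structure_probability(empty, "AAAA", m), 1.0)
  set.seed(47)
  for (s in c("GGGAAACCC", random_seq(12), random_seq(15))) {
    en <- enumerate_structures(s, m)
    ps <- vapply(en, function(e) structure_probability(e$structure, s, m), numeric(1))
    expect_equal(sum(ps), 1, tolerance = 1e-12, info = s)
    # ratio law for the first two structures
    if (length(en) >= 2) {
      lhs <- ps[1] / ps[2]
      rhs <- exp(-(en[[1]]$energy - en[[2]]$energy) / m$kT)
      expect_equal(lhs, rhs, tolerance = 1e-9)
    }
  }
  expect_error(structure_probability(empty, "GGGG", m), "not compatible")
})

test_that("DP minimum free energy equals the enumeration minimum", {
  m <- energy_model()
  r0 <- mfe("AAAA", m)
  expect_equal(r0$energy, 0)
  expect_equal(nrow(r0$structure$pairs), 0L)
  set.seed(53)
  for (r in 1:20) {
    s <- random_seq(sample(8:16, 1))
    en <- enumeration_partition_function(s, m)
    got <- mfe(s, m)
    expect_equal(got$energy, min(en$energies), tolerance = 1e-9, info = s)
    # the reported structure scores its reported energy
    expect_equal(structure_free_energy(got$structure, m), got$energy,
                 tolerance = 1e-9)
  }
  # deterministic traceback
  s <- "GGGAAACCCGGGAAACCC"
  expect_identical(mfe(s, m)$dotbracket, mfe(s, m)$dotbracket)
})

test_that("the sensor hairpins fold as designed: one stable stem over the recognition site", {
  p <- load_panel("builtin")
  m <- energy_model()
  for (nm in c("H1", "H2")) {
    r <- mfe(p[[nm]], m)
    expect_lt(r$energy, 0)
    kinds <- vapply(decompose_loops(r$structure), `[[`, character(1), "kind")
    expect_equal(sum(kinds == "hairpin"), 1L)       # a single stem-loop
    expect_equal(sum(kinds == "multiloop"), 0L)
    d <- longest_complementary_duplex(p[[nm]], p$S)
    seg <- d$start_a:(d$start_a + d$length - 1L)
    paired <- rep(FALSE, nchar(p[[nm]]$bases))
    paired[as.vector(r$structure$pairs)] <- TRUE
    # the stem sequesters most of the S-recognition segment (the toehold
    # stays open by design)
    expect_gte(mean(paired[seg]), 0.5)
  }
})

test_that("seeded hairpin panels fold into their designed stems", {
  m <- energy_model()
  panel <- random_hairpin_panel(stem_len = 4, loop_len = 4, count = 6, seed = 19)
  for (s in panel) {
    expect_equal(nchar(s$bases), 12L)
    n <- 12L
    designed <- secondary_structure(s$bases,
                                    cbind(1:4, n:(n - 3L)))
    r <- mfe(s, m)
    expect_lt(r$energy, 0)
    # the designed full stem attains the ensemble minimum
    expect_equal(structure_free_energy(designed, m), r$energy, tolerance = 1e-9)
  }
  expect_identical(random_hairpin_panel(seed = 3)$hp1$bases,
                   random_hairpin_panel(seed = 3)$hp1$bases)
  expect_error(random_hairpin_panel(loop_len = 2), "loop_len")
})
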