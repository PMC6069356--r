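test_that("complex enumeration counts rotation classes and honors the guard", {
  expect_equal(nrow(enumerate_complexes("A", 2)), 2L)           # A, A.A
  expect_equal(nrow(enumerate_complexes(c("A", "B", "C"), 2)), 9L)
  e4 <- enumerate_complexes(c("S", "H1", "H2"), 4)
  expect_equal(nrow(e4), 44L)  # 3 + 6 + 11 + 24 necklaces
  expect_true("H1.H2.H1.H2" %in% e4$complex)
  expect_true(any(vapply(e4$strands, function(v) {
    length(v) == 3 && setequal(v, c("S", "H1", "H2"))
  }, logical(1))))
  # monomers always present; symmetry orders correct
  expect_true(all(c("S", "H1", "H2") %in% e4$complex))
  expect_equal(e4$symmetry[e4$complex == "H1.H2.H1.H2"], 2L)
  expect_equal(e4$symmetry[e4$complex == "H1.H1.H1.H1"], 4L)
  expect_equal(e4$symmetry[e4$complex == "H1.H2"], 1L)
  expect_error(enumerate_complexes("A", 0), "max_size")
  # deterministic order
  expect_identical(enumerate_complexes(c("S", "H1"), 3)$complex,
                   enumerate_complexes(c("S", "H1"), 3)$complex)
})

test_that("complex partition functions match enumeration over connected structures", {
  m <- energy_model()
  # monomer consistency with the single-strand route
  expect_equal(complex_partition_function("GGGAAACCC", model = m),
               partition_function("GGGAAACCC", m), tolerance = 1e-12)
  # no inter-strand pairs -> no connected structure
  expect_equal(complex_partition_function(c("AAAA", "AAAA"), model = m), 0)
  expect_identical(complex_partition_function(c("AAAA", "AAAA"), model = m,
                                              log = TRUE), -Inf)
  # exhaustive oracle on small complexes, incl. the symmetry correction
  cases <- list(c("GGG", "CCC"), c("GCGC", "GCGC"), c("GGGAA", "TTCCC"),
                c("GGCC", "GGCC", "GGCC"), c("GGAA", "TT", "CC"))
  for (cx in cases) {
    en <- enumeration_partition_function(paste(cx, collapse = "+"), m,
                                         connected_only = TRUE)
    v <- chaforge:::rotational_symmetry(cx)
    expect_equal(complex_partition_function(cx, model = m), en$Q / v,
                 tolerance = 1e-11, info = paste(cx, collapse = "+"))
  }
})

test_that("equilibrium solving matches the dimer closed form on a grid", {
  grid <- expand.grid(logK = seq(2, 20, length.out = 5),
                      a0 = c(1e-9, 5e-8, 3e-7, 1e-6),
                      b0 = c(1e-9, 1e-7, 2e-6))
  cx <- tibble::tibble(
    complex = c("A", "B", "A.B"),
    strands = list("A", "B", c("A", "B")),
    size = c(1L, 1L, 2L),
    symmetry = c(1L, 1L, 1L),
    logQ = c(0, 0, NA_real_)
  )
  for (r in seq_len(nrow(grid))) {
    K <- exp(grid$logK[r])
    cx$logQ[3] <- log(K)
    tb <- tube(c(A = grid$a0[r], B = grid$b0[r]) * 1e9, max_size = 2)
    eq <- solve_equilibrium(tb, cx)
    want <- oracle_dimer(grid$a0[r], grid$b0[r], K)
    got <- setNames(eq$species$x_M, eq$species$complex)[c("A", "B", "A.B")]
    expect_equal(unname(got), unname(want), tolerance = 1e-9,
                 info = sprintf("K=%g a0=%g b0=%g", K, grid$a0[r], grid$b0[r]))
    expect_lte(eq$diagnostics$residual, 1e-8)
    expect_lte(eq$diagnostics$kkt, 1e-6)
  }
})

test_that("single strand with only its monomer is fixed by conservation", {
  cx <- tibble::tibble(complex = "A", strands = list("A"), size = 1L,
                       symmetry = 1L, logQ = 3.7)
  eq <- solve_equilibrium(tube(c(A = 123)), cx)
  expect_equal(eq$species$x_nM, 123, tolerance = 1e-10)
})

test_that("random tubes conserve mass, satisfy the mass-action certificate, and descend", {
  m <- energy_model()
  set.seed(61)
  panel <- random_hairpin_panel(stem_len = 5, loop_len = 4, count = 3, seed = 67)
  cx <- enumerate_complexes(names(panel), 3)
  cx$logQ <- vapply(cx$strands, function(v) {
    complex_partition_function(v, panel, m, log = TRUE)
  }, numeric(1))
  for (r in 1:5) {
    totals <- setNames(stats::runif(3, 10, 500), names(panel))
    eq <- solve_equilibrium(tube(totals, 3), cx)
    # A x = x0 to 1e-8 relative
    A <- vapply(eq$species$strands, function(v) {
      vapply(names(totals), function(s) sum(v == s), numeric(1))
    }, numeric(3))
    recovered <- drop(A %*% eq$species$x_nM)
    expect_equal(unname(recovered), unname(totals), tolerance = 1e-8)
    expect_lte(eq$diagnostics$kkt, 1e-6)
    expect_true(all(eq$species$x_M >= 0))
    # line-searched dual objective decreases monotonically
    tr <- eq$diagnostics$objective_trace
    if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-12 * pmax(abs(tr[-1]), 1)))
  }
})

test_that("the sensor tube is dominated by the designed product over by-products", {
  p <- load_panel("builtin")
  eq <- analyze_tube(p, tube(c(S = 50, H1 = 300, H2 = 300), max_size = 4))
  sp <- eq$species
  expect_lte(eq$diagnostics$residual, 1e-8)
  expect_lte(eq$diagnostics$kkt, 1e-6)
  h1h2 <- sp$x_nM[sp$complex == "H1.H2"]
  byproducts <- sp$x_nM[sp$size >= 2 & sp$complex != "H1.H2"]
  expect_true(all(h1h2 > byproducts))
  # specifically: the trimer and tetramer by-products named in the design
  expect_gt(h1h2, sp$x_nM[sp$complex == "H1.H2.H1.H2"])
  expect_gt(h1h2, max(sp$x_nM[sp$size == 3]))
})
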