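test_that("dot-bracket parse/render round-trips and validates", {
  st <- parse_dotbracket("GGGAAAACCC", "(((....)))")
  expect_equal(nrow(st$pairs), 3L)
  expect_equal(format_dotbracket(st), "(((....)))")
  # multi-strand with nick
  st2 <- parse_dotbracket("GGG+CCC", "(((+)))")
  expect_equal(st2$nicks, 3L)
  expect_equal(format_dotbracket(st2), "(((+)))")
  set.seed(7)
  for (r in 1:10) {
    s <- random_seq(12)
    en <- enumerate_structures(s)
    pick <- en[[sample(length(en), 1)]]$structure
    expect_equal(parse_dotbracket(s, format_dotbracket(pick))$pairs, pick$pairs)
  }
  expect_error(parse_dotbracket("ACGT", "(().."), "match")
  expect_error(parse_dotbracket("ACGT", "()(."), "unbalanced")
  expect_error(parse_dotbracket("ACGT", "))(("), "unbalanced")
  expect_error(secondary_structure("ACGTACGT", rbind(c(1, 5), c(3, 7))), "crossing")
  expect_error(secondary_structure("ACGT", rbind(c(1, 4), c(1, 3))), "at most one pair")
  expect_error(secondary_structure("ACGT", rbind(c(1, 9))), "bounds")
})

test_that("loop decomposition partitions bases into the canonical kinds", {
  # empty structure: single exterior loop owning every base
  lo <- decompose_loops(secondary_structure("ACGTACGT"))
  expect_length(lo, 1L)
  expect_equal(lo[[1]]$kind, "exterior")
  expect_equal(lo[[1]]$members, 1:8)

  # 4-bp stem, 4-nt hairpin loop: 3 stacks + 1 hairpin + exterior
  st <- parse_dotbracket("GGGGAAAACCCC", "((((....))))")
  kinds <- vapply(decompose_loops(st), `[[`, character(1), "kind")
  expect_equal(sort(kinds),
               sort(c("exterior", "stack", "stack", "stack", "hairpin")))

  # single unpaired base on one side: exactly one bulge
  st2 <- parse_dotbracket("GGAGGAAAACCCC", "((.((....))))")
  kinds2 <- vapply(decompose_loops(st2), `[[`, character(1), "kind")
  expect_equal(sum(kinds2 == "bulge"), 1L)

  # interior loop and multiloop
  st3 <- parse_dotbracket("GGAAGGAAAACCAACC", "((..((....))..))")
  expect_equal(sum(vapply(decompose_loops(st3), `[[`, character(1), "kind") == "interior"), 1L)
  st4 <- parse_dotbracket("GGGGAAACCCGGGAAACCCC",
                          "((((...)))(((...))))")
  kinds4 <- vapply(decompose_loops(st4), `[[`, character(1), "kind")
  expect_equal(sum(kinds4 == "multiloop"), 1L)

  # every base in exactly one loop, for random enumerated structures
  set.seed(13)
  for (r in 1:10) {
    s <- random_seq(14)
    en <- enumerate_structures(s)
    pick <- en[[sample(length(en), 1)]]$structure
    members <- unlist(lapply(decompose_loops(pick), `[[`, "members"))
    expect_equal(sort(members), 1:14)
  }
})

test_that("undersized hairpins are rejected unless opened by a nick", {
  expect_error(decompose_loops(secondary_structure("GAAC", rbind(c(1, 4)))),
               "minimum 3")
  # the same closing pair across a nick is an exterior loop: no minimum
  st <- secondary_structure(c("GA", "AC"), rbind(c(1, 4)))
  lo <- decompose_loops(st)
  expect_equal(vapply(lo, `[[`, character(1), "kind")[2], "exterior")
})

test_that("structure free energy is the sum of its loop terms", {
  m <- energy_model()
  expect_identical(structure_free_energy(secondary_structure("ACGTACGT"), m), 0)
  # 3-stack helix with a 4-nt hairpin: hand-summed table lookup
  st <- parse_dotbracket("GGGGAAAACCCC", "((((....))))")
  manual <- m$stack["G", "G"] * 3 + m$hairpin[4]
  expect_equal(structure_free_energy(st, m), manual, tolerance = 1e-12)
  # definitional consistency on random enumerated structures
  set.seed(17)
  for (r in 1:8) {
    s <- random_seq(13)
    for (e in enumerate_structures(s, m)[1:5]) {
      if (is.null(e)) next
      bases <- strsplit(s, "")[[1]]
      manual <- sum(vapply(decompose_loops(e$structure),
                           chaforge:::loop_energy, numeric(1),
                           bases = bases, model = m))
      expect_equal(e$energy, manual, tolerance = 1e-12)
    }
  }
})

test_that("stabilizing stacks never raise the energy (table sanity)", {
  m <- energy_model()
  expect_true(all(m$stack < 0))
  # extending a helix by one stack lowers the energy when the hairpin term
  # is unchanged
  st1 <- parse_dotbracket("GGGGAAAACCCC", "(((.....))).")
  st2 <- parse_dotbracket("GGGGAAAACCCC", "((((....))))")
  expect_lt(structure_free_energy(st2, m) - structure_free_energy(st1, m),
            m$hairpin[4] - m$hairpin[5] + 1e-9)
})

test_that("oversized loops are scored finitely by extrapolation, never an error", {
  m <- energy_model()
  mk <- function(u) {
    structure_free_energy(
      parse_dotbracket(paste0("GG", strrep("A", u), "CC"),
                       paste0("((", strrep(".", u), "))")), m)
  }
  expect_true(is.finite(mk(40)))
  expect_gt(mk(40), mk(30))  # larger loop, larger penalty
  expect_equal(mk(40) - mk(30), m$js_coef * log(40 / 30), tolerance = 1e-12)
})
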