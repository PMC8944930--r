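test_that("nucleosome compaction matches closed form and handles edge cases", {
  expect_equal(compaction_from_nucleosome(15, 0.34, 146), 15 * 0.34 / 161)
  expect_equal(round(compaction_from_nucleosome(15, 0.34, 146), 4), 0.0317)
  expect_equal(compaction_from_nucleosome(15, 0.34, 0), 0.34)
  expect_equal(round(compaction_from_nucleosome(30, 0.34, 146), 4), 0.0580)
  expect_error(compaction_from_nucleosome(0, 0.34, 0), "positive")
  expect_error(compaction_from_nucleosome(-5, 0.34, 146), "positive")
})

test_that("compaction is degree-1 in rise and invariant to joint bp scaling", {
  for (s in c(0.5, 2, 7)) {
    expect_equal(compaction_from_nucleosome(15, s * 0.34, 146),
                 s * compaction_from_nucleosome(15, 0.34, 146))
    expect_equal(compaction_from_nucleosome(s * 15, 0.34, s * 146),
                 compaction_from_nucleosome(15, 0.34, 146))
  }
})

test_that("bp/Kuhn conversion and equivalent Kuhn length", {
  pp <- polymer_params()
  expect_equal(bp_to_kuhn(0, pp), 0)
  expect_equal(bp_to_kuhn(116000, pp), 116000 * 0.0317 / 250)
  expect_equal(round(bp_to_kuhn(116000, pp), 2), 14.71)
  expect_equal(round(bp_to_kuhn(343000, pp), 2), 43.49)
  expect_error(bp_to_kuhn(-1, pp), "nonnegative")

  expect_equal(equivalent_kuhn_length(250, 0.0317, 0.0317), 250)
  expect_equal(round(equivalent_kuhn_length(250, 0.0317, 1 / 65)), 121)
  expect_equal(round(equivalent_kuhn_length(250, 0.0317, 1 / 53)), 149)
  ## segment-count preservation: (c -> c_alt, b -> b c_alt / c) round-trips
  for (c_alt in c(1 / 65, 1 / 53, 0.1)) {
    b2 <- equivalent_kuhn_length(250, 0.0317, c_alt)
    p1 <- polymer_params(kuhn_length_b = 250, compaction_c = 0.0317)
    p2 <- polymer_params(kuhn_length_b = b2, compaction_c = c_alt)
    expect_equal(bp_to_kuhn(577000, p1), bp_to_kuhn(577000, p2))
  }
  expect_equal(loop_tip_extension(25, 16), 400)
})

test_that("chromosome specs validate and the packaged table resolves loci", {
  expect_error(chromosome_spec("x", 100, 150, 50), "centromere")
  expect_error(chromosome_spec("x", 100, 50, 150), "locus")
  tab <- yeast_chromosomes()
  expect_setequal(tab$locus_name, c("URA3", "LYS2"))
  ura <- lookup_chromosome("URA3")
  expect_equal(ura$length_bp, 577000)
  expect_equal(ura$locus_bp, 116000)
  lys <- lookup_chromosome("chrII")
  expect_equal(lys$length_bp - lys$locus_bp, 343000)  # 343 kb to telomere
  expect_error(lookup_chromosome("HIS3"), "unknown")
})

test_that("polymer params enforce invariants", {
  pp <- polymer_params()
  expect_equal(pp$mscd_floor, 0.0625)
  expect_error(polymer_params(alpha = 0), "positive")
  expect_error(polymer_params(alpha = 1.5), "alpha")
  expect_error(polymer_params(D0 = -1), "positive")
})

test_that("topology classification follows the tether-path construction", {
  expect_equal(classify_topology(numeric(0), 10)$topology, "unlinked")
  lin <- classify_topology(c(4), 10)
  expect_equal(lin$topology, "linear")
  expect_equal(unname(lin$segments["nL"]), 12)
  ring <- classify_topology(c(4, 13), 10)
  expect_equal(ring$topology, "ring")
  expect_equal(unname(ring$segments), c(12, 6))
  ## multiple linkages: only the nearest on each side matters
  ring2 <- classify_topology(c(1, 4, 13, 30), 10)
  expect_equal(unname(ring2$segments), c(12, 6))
  pin <- classify_topology(c(10), 10)
  expect_true(pin$pinned)
  expect_equal(unname(pin$segments), c(0, 0))
})

test_that("topology classification is reflection invariant about the locus", {
  set.seed(42)
  for (i in 1:25) {
    locus <- runif(1, 5, 45)
    pos <- runif(rpois(1, 3), 0, 50)
    a <- classify_topology(pos, locus)
    b <- classify_topology(2 * locus - pos, locus)
    expect_equal(a$topology, b$topology)
    expect_equal(sort(unname(a$segments)), sort(unname(b$segments)))
  }
})

test_that("sampled cells have Poisson linkages at uniform positions", {
  ch <- lookup_chromosome("URA3")
  pp <- polymer_params()
  n_kuhn <- bp_to_kuhn(ch$length_bp, pp)
  set.seed(102)
  cells <- replicate(10000, sample_cell(ch, pp, 3.36, 0.3), simplify = FALSE)
  counts <- vapply(cells, function(x) length(x$linkage_positions), 1L)
  ## law of large numbers: empirical mean within 3 SE of 3.36
  se <- sqrt(3.36 / 10000)
  expect_lt(abs(mean(counts) - 3.36), 3 * se)
  ## Poisson dispersion: Var ~= mean
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.05)
  ## positions uniform over [0, N]: chi-squared GOF at the 1% level
  pos <- unlist(lapply(cells, function(x) x$linkage_positions))
  ct <- table(cut(pos, breaks = seq(0, n_kuhn, length.out = 11)))
  expect_gt(chisq.test(ct)$p.value, 0.01)
  ## rabl frequency near 0.3, topology consistent with positions
  expect_lt(abs(mean(vapply(cells, `[[`, TRUE, "rabl")) - 0.3), 0.02)
  for (cell in cells[1:50]) {
    ref <- classify_topology(cell$linkage_positions, cell$locus_kuhn)
    expect_equal(cell$topology, ref$topology)
    expect_equal(cell$segments, ref$segments)
  }
})

test_that("sample_cell degenerate and invalid inputs", {
  ch <- lookup_chromosome("URA3")
  pp <- polymer_params()
  set.seed(1)
  for (i in 1:20) {
    cell <- sample_cell(ch, pp, 0, 0)
    expect_equal(cell$topology, "unlinked")
    expect_false(cell$rabl)
  }
  expect_error(sample_cell(ch, pp, -1, 0), "mu")
  expect_error(sample_cell(ch, pp, 1, 1.5), "p_rabl")
})
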