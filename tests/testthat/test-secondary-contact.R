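test_that("demography configuration enforces epoch ordering and Ne conservation", {
  cfg <- demographyConfig()
  expect_equal(cfg$tSplit, 100000)
  expect_equal(cfg$tExpand, 10000)
  expect_equal(2 * cfg$demesPerSide * cfg$nePerDeme, 100000)  # total Ne
  expect_error(demographyConfig(tSplit = 5000, tExpand = 10000), "tSplit")
  expect_error(demographyConfig(tExpand = 0), "tExpand")
})

test_that("simulated datasets are segregating, reproducible, biallelic", {
  cfg <- demographyConfig(nLoci = 40, seed = 3)
  ds <- simulateSecondaryContact(cfg)
  expect_equal(nSites(ds), 40)
  expect_equal(nLoci(ds), 40)
  for (j in seq_len(40)) {
    tot <- colSums(alleleCounts(ds, j))
    expect_true(all(tot > 0))  # segregating in the total sample
    expect_equal(sum(tot), 40 * 40)
  }
  ds2 <- simulateSecondaryContact(cfg)
  expect_identical(ds@counts, ds2@counts)
})

test_that("isolation without gene flow separates the two sides", {
  # with 4Nm = 0 every deme drifts independently, so deme-level FST is high
  # everywhere; the isolation signal lives in the side-level frequencies.
  # Compare side vs side and half vs half at matched 10-deme pooling (which
  # averages out deme-level drift), on common polymorphisms where the
  # split-era signal resides.
  cfg <- demographyConfig(fourNm = 0, nLoci = 150, copiesPerDeme = 20,
                          seed = 5)
  ds <- simulateSecondaryContact(cfg)
  vals <- vapply(seq_len(150), function(j) {
    m <- alleleCounts(ds, j)
    pool <- function(rows) colSums(m[rows, , drop = FALSE])
    c(unname(colSums(m)[1] / sum(m)),
      unname(wcFst(rbind(pool(1:10), pool(21:30)))),
      mean(c(wcFst(rbind(pool(1:10), pool(11:20))),
             wcFst(rbind(pool(21:30), pool(31:40)))), na.rm = TRUE))
  }, c(0, 0, 0))
  common <- vals[1, ] > 0.15 & vals[1, ] < 0.85
  between <- mean(vals[2, common], na.rm = TRUE)
  within <- mean(vals[3, common], na.rm = TRUE)
  expect_gt(between, 0.3)
  expect_gt(between / within, 3)
})

test_that("a vanishing history degenerates to panmixia", {
  cfg <- demographyConfig(tExpand = 1, tSplit = 2, fourNm = 4, nLoci = 150,
                          copiesPerDeme = 10, seed = 7)
  ds <- simulateSecondaryContact(cfg)
  f <- vapply(seq_len(150), function(j) wcFst(alleleCounts(ds, j)), 0)
  expect_lt(abs(mean(f[is.finite(f)])), 0.02)
  # and the LRT-only clinal rate collapses to its type-I level
  pc <- percentClinal(ds, criterion = "lrt")
  expect_gte(pc, 0.01); expect_lte(pc, 0.12)
})

test_that("panmictic-limit heterozygosity matches the single-site expectation", {
  # one uniformly placed mutation: E[He] = ((n-1)/n) / H_{n-1} under the
  # neutral frequency spectrum (site picked proportional to branch length).
  # The structured epoch is made negligibly short (and deme sizes small, so
  # the event-driven simulation stays cheap) leaving a single panmictic
  # ancestor; the expectation is independent of Ne.
  cfg <- demographyConfig(tExpand = 10, tSplit = 11, fourNm = 40,
                          nePerDeme = 250,
                          nLoci = 400, copiesPerDeme = 10, seed = 9)
  ds <- simulateSecondaryContact(cfg)
  he <- vapply(seq_len(400), function(j) {
    tot <- colSums(alleleCounts(ds, j))
    expectedHet(tot / sum(tot))
  }, 0)
  n <- 400
  expected <- ((n - 1) / n) / sum(1 / seq_len(n - 1))
  expect_equal(mean(he), expected, tolerance = 0.08)
})

test_that("neutral clines balance sign and center at the contact point", {
  cfg <- demographyConfig(fourNm = 4, nLoci = 300, seed = 13)
  ds <- simulateSecondaryContact(cfg)
  tab <- percentClinal(ds, details = TRUE)
  clin <- tab[!is.na(tab$clinal) & tab$clinal, ]
  expect_gt(nrow(clin), 50)
  # equal numbers of positive and negative slopes
  st <- binom.test(sum(clin$slope > 0), nrow(clin))
  expect_gt(st$p.value, 0.01)
  # midpoints concentrate at the contact zone (between demes 20 and 21)
  expect_lt(abs(median(clin$midpoint) - 20.5), 2)
})

test_that("the chain is exchangeable under reversal", {
  cfg <- demographyConfig(fourNm = 4, nLoci = 80, seed = 15)
  ds <- simulateSecondaryContact(cfg)
  rev <- ds[rev(seq_len(40)), ]
  rev@sites$latitude <- as.numeric(seq_len(40))
  rownamesFix <- sprintf("deme%02d", seq_len(40))
  rev@sites$id <- rownamesFix
  a <- percentClinal(ds)
  b <- percentClinal(rev)
  expect_lt(abs(a - b), 0.05)
})

test_that("the simulation study summarizes dispersal effects", {
  cfgs <- list(demographyConfig(fourNm = 0.4, nLoci = 100, seed = 19),
               demographyConfig(fourNm = 40, nLoci = 100, seed = 19))
  study <- runSimulationStudy(cfgs, nReplicates = 2)
  expect_equal(nrow(study$summary), 4)
  agg <- aggregate(medianAbsSlope ~ fourNm, study$summary, mean)
  # higher dispersal, shallower clines
  expect_lt(agg$medianAbsSlope[agg$fourNm == 40],
            agg$medianAbsSlope[agg$fourNm == 0.4])
  # sign-normalized study fits put the high-frequency end on the left
  expect_true(all(study$fits$slope <= 0))
})

test_that("the coalescent engine agrees with an independent simulator", {
  # same split/expand stepping-stone history at toy scale, simulated with
  # msprime (python) as the external oracle; compare the derived-allele
  # frequency distribution and between-half differentiation
  py <- c(
    "import msprime, numpy as np",
    "D, ne, t_exp, t_split, m = 6, 500, 1000, 5000, 2/(4*500)",
    "dem = msprime.Demography()",
    "for i in range(D): dem.add_population(name=f'd{i}', initial_size=ne)",
    "dem.add_population(name='r1', initial_size=3*ne)",
    "dem.add_population(name='r2', initial_size=3*ne)",
    "dem.add_population(name='anc', initial_size=6*ne)",
    "for i in range(D-1):",
    "    dem.set_migration_rate(f'd{i}', f'd{i+1}', m)",
    "    dem.set_migration_rate(f'd{i+1}', f'd{i}', m)",
    "dem.add_population_split(time=t_exp, derived=[f'd{i}' for i in range(3)], ancestral='r1')",
    "dem.add_population_split(time=t_exp, derived=[f'd{i}' for i in range(3,6)], ancestral='r2')",
    "dem.add_population_split(time=t_split, derived=['r1','r2'], ancestral='anc')",
    "dem.sort_events()",
    "rng = np.random.default_rng(7)",
    "out = []",
    "for ts in msprime.sim_ancestry(samples={f'd{i}': 10 for i in range(D)},",
    "        demography=dem, ploidy=1, num_replicates=400, random_seed=11):",
    "    t = ts.first()",
    "    nodes = [u for u in t.nodes() if t.parent(u) != -1]",
    "    L = np.array([t.branch_length(u) for u in nodes])",
    "    node = nodes[rng.choice(len(nodes), p=L/L.sum())]",
    "    cnt = np.zeros(D, dtype=int)",
    "    for s in t.samples(node): cnt[ts.node(s).population] += 1",
    "    out.append(cnt)",
    "print('\\n'.join(' '.join(map(str, r)) for r in out))")
  scriptFile <- tempfile(fileext = ".py")
  writeLines(py, scriptFile)
  mspRaw <- system2("python", scriptFile, stdout = TRUE)
  msp <- do.call(rbind, lapply(strsplit(mspRaw, " "), as.integer))

  mine <- clineCoCo:::simSecondaryContactLoci(
    demesPerSide = 3, nePerDeme = 500, fourNm = 2, tExpand = 1000,
    tSplit = 5000, copiesPerDeme = 10, nLoci = 400)

  stat <- function(d) {
    p <- rowSums(d) / 60
    half <- cbind(rowSums(d[, 1:3]), rowSums(d[, 4:6]))
    fst <- apply(half, 1, function(h)
      wcFst(rbind(c(h[1], 30 - h[1]), c(h[2], 30 - h[2]))))
    c(meanP = mean(p), sdP = sd(p),
      rare = mean(p < 0.1), fst = mean(fst, na.rm = TRUE))
  }
  a <- stat(msp); b <- stat(mine)
  expect_lt(abs(a["meanP"] - b["meanP"]), 0.05)
  expect_lt(abs(a["sdP"] - b["sdP"]), 0.05)
  expect_lt(abs(a["rare"] - b["rare"]), 0.08)
  expect_lt(abs(a["fst"] - b["fst"]), 0.08)
})
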