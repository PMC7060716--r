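test_that("a planted backbone amide near N1 yields one Watson-Crick bond", {
  rc <- adenineCoords()
  u <- outwardDir("N1")
  cs <- makeAdenineWith("planted_n1",
                        glyDonorAt(rc["N1", ] + 2.9 * u, u, resseq = 12L))
  inst <- matchFragment(cs)[[1L]]
  hb <- detectHBonds(cs, inst)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$fragment_atom, "N1")
  expect_equal(hb$descriptor, "backbone_N")
  expect_equal(hb$direction, "fragment_accepts")
  expect_equal(hb$edge, "watson_crick")
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
})

test_that("the distance cutoff is enforced and configurable", {
  rc <- adenineCoords()
  u <- outwardDir("N1")
  cs <- makeAdenineWith("far_n1",
                        glyDonorAt(rc["N1", ] + 4.2 * u, u, resseq = 12L))
  inst <- matchFragment(cs)[[1L]]
  expect_equal(nrow(detectHBonds(cs, inst)), 0L)
  hb <- detectHBonds(cs, inst, params = hbondParams(maxDaDistance = 4.4))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 4.2, tolerance = 1e-6)
  expect_error(hbondParams(maxDaDistance = 5.0), "within")
})

test_that("an aspartate side-chain oxygen accepts from N6", {
  g <- generateSite(motifPlan("asp", seed = 21L))
  s <- buildSite(g$structure, matchFragment(g$structure)[[1L]])
  n6 <- hbonds(s)[hbonds(s)$fragment_atom == "N6", ]
  expect_equal(nrow(n6), 1L)
  expect_equal(n6$descriptor, "sidechain_O")
  expect_equal(n6$direction, "fragment_donates")
  expect_equal(n6$partner_resname, "ASP")
})

test_that("the antecedent angle rejects partners buried behind the donor", {
  rc <- adenineCoords()
  u <- outwardDir("N1")
  # amide N 2.9 A from N1 but with its CA placed between N and the
  # fragment: the CA-N...N1 angle collapses below 90 degrees
  pos <- rc["N1", ] + 2.9 * u
  res <- rbind(protRow("N", "N", pos, resseq = 12L),
               protRow("CA", "C", pos - 1.46 * u, resseq = 12L))
  cs <- makeAdenineWith("buried", res)
  inst <- matchFragment(cs)[[1L]]
  expect_equal(nrow(detectHBonds(cs, inst)), 0L)
  relaxed <- hbondParams(minAntecedentAngle = 0)
  expect_equal(nrow(detectHBonds(cs, inst, params = relaxed)), 1L)
})

test_that("water bridges need a protein partner and a single water", {
  rc <- adenineCoords()
  u <- outwardDir("N7")
  # planted bridge: water 2.8 A from N7, backbone O 2.7 A beyond
  wpos <- rc["N7", ] + 2.8 * u
  cs <- makeAdenineWith("bridge", rbind(
    glyAcceptorAt(wpos + 2.7 * u, u, resseq = 30L), watRow(wpos)))
  inst <- matchFragment(cs)[[1L]]
  hb <- detectWaterMediated(cs, inst)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$fragment_atom, "N7")
  expect_equal(hb$edge, "hoogsteen")
  expect_equal(hb$descriptor, "backbone_O")
  expect_true(hb$water_mediated)
  expect_false(is.na(hb$bridge_water))
  expect_equal(hb$distance, 2.8, tolerance = 1e-6)
  expect_equal(hb$leg2, 2.7, tolerance = 1e-6)

  # dangling water: no protein within reach of the water
  cs2 <- makeAdenineWith("dangling", watRow(wpos))
  expect_equal(nrow(detectWaterMediated(cs2,
                                        matchFragment(cs2)[[1L]])), 0L)

  # two chained waters do not bridge
  w2 <- wpos + 2.7 * u
  cs3 <- makeAdenineWith("chain", rbind(
    watRow(wpos, 1L), watRow(w2, 2L),
    glyAcceptorAt(w2 + 2.7 * u, u, resseq = 30L)))
  hb3 <- detectWaterMediated(cs3, matchFragment(cs3)[[1L]])
  expect_equal(nrow(hb3), 0L)
})

test_that("buildSite merges, deduplicates and fills canonical coordinates", {
  rc <- adenineCoords()
  u1 <- outwardDir("N1"); u6 <- outwardDir("N6"); u7 <- outwardDir("N7")
  rot <- function(v, deg) {
    a <- deg * pi / 180
    c(cos(a) * v[1L] - sin(a) * v[2L], sin(a) * v[1L] + cos(a) * v[2L], 0)
  }
  wpos <- rc["N7", ] + 2.8 * u7
  offset_n1 <- 2.9 * u1
  extras <- rbind(
    glyDonorAt(rc["N1", ] + offset_n1, u1, resseq = 12L),
    glyAcceptorAt(rc["N6", ] + 2.9 * rot(u6, 55), rot(u6, 55),
                  resseq = 10L),
    glyDonorAt(rc["N3", ] + 2.9 * outwardDir("N3"), outwardDir("N3"),
               resseq = 40L),
    glyAcceptorAt(wpos + 2.7 * u7, u7, resseq = 30L),
    watRow(wpos))
  cs0 <- makeAdenineWith("merge0", extras)
  # move the whole complex so the canonical transform is nontrivial
  move <- eulerTransform(c(0.4, -0.9, 1.7), c(3, -7, 11))
  at <- atoms(cs0)
  at[, c("x", "y", "z")] <-
    applyTransform(move, as.matrix(at[, c("x", "y", "z")]))
  cs <- new("ComplexStructure", id = "merge", atoms = at,
            ligandInstances = ligandInstances(cs0), modelNumber = 1L)
  s <- buildSite(cs, matchFragment(cs)[[1L]])
  expect_equal(nrow(hbonds(s)), 4L)       # 3 direct + 1 mediated
  expect_equal(sum(hbonds(s)$water_mediated), 1L)
  expect_equal(nrow(partnerCoords(s)), 4L)
  # canonical coordinates reproduce the planted offsets analytically
  i_n1 <- which(hbonds(s)$fragment_atom == "N1")
  expect_equal(unname(partnerCoords(s)[i_n1, ]),
               unname(rc["N1", ] + offset_n1), tolerance = 1e-6)
  i_w <- which(hbonds(s)$water_mediated)
  expect_equal(unname(partnerCoords(s)[i_w, ]), unname(wpos),
               tolerance = 1e-6)
})

test_that("a direct bond wins over a mediated bond to the same partner", {
  rc <- adenineCoords()
  u <- outwardDir("N6")
  opos <- rc["N6", ] + 3.3 * u          # direct N6 donor -> carbonyl O
  wpos <- rc["N6", ] + 2.0 * u + c(0, 0, 2.0)  # water bridging the same O
  stopifnot(sqrt(sum((wpos - opos)^2)) < 3.5)
  cs <- makeAdenineWith("dedup", rbind(glyAcceptorAt(opos, u, resseq = 30L),
                                       watRow(wpos)))
  inst <- matchFragment(cs)[[1L]]
  expect_equal(nrow(detectWaterMediated(cs, inst)), 1L)
  s <- buildSite(cs, inst)
  hb7 <- hbonds(s)[hbonds(s)$fragment_atom == "N6" &
                     hbonds(s)$descriptor == "backbone_O", ]
  expect_equal(nrow(hb7), 1L)
  expect_false(hb7$water_mediated)        # direct beats mediated
})

test_that("the 3.2 / 3.5 / 3.9 A bond sets are nested", {
  rc <- adenineCoords()
  extras <- rbind(
    glyDonorAt(rc["N1", ] + 3.0 * outwardDir("N1"), outwardDir("N1"),
               resseq = 10L),
    glyDonorAt(rc["N3", ] + 3.35 * outwardDir("N3"), outwardDir("N3"),
               resseq = 20L),
    glyDonorAt(rc["N7", ] + 3.7 * outwardDir("N7"), outwardDir("N7"),
               resseq = 30L))
  cs <- makeAdenineWith("nesting", extras)
  inst <- matchFragment(cs)[[1L]]
  key <- function(hb) paste(hb$fragment_atom, hb$partner_serial)
  sets <- lapply(c(3.2, 3.5, 3.9), function(d)
    key(detectHBonds(cs, inst, params = hbondParams(maxDaDistance = d))))
  expect_length(sets[[1L]], 1L)
  expect_length(sets[[2L]], 2L)
  expect_length(sets[[3L]], 3L)
  expect_true(all(sets[[1L]] %in% sets[[2L]]))
  expect_true(all(sets[[2L]] %in% sets[[3L]]))
  # and on generated fixtures too
  for (seed in 1:5) {
    g <- generateSite(randomPlan(seed))
    ins <- matchFragment(g$structure)[[1L]]
    ss <- lapply(c(3.2, 3.5, 3.9), function(d)
      key(detectHBonds(g$structure, ins,
                       params = hbondParams(maxDaDistance = d))))
    expect_true(all(ss[[1L]] %in% ss[[2L]]))
    expect_true(all(ss[[2L]] %in% ss[[3L]]))
  }
})

test_that("partners at N1, N7 and N3 cover all three binding edges", {
  plan <- sitePlan(data.frame(
    fragment_atom = c("N1", "N7", "N3"),
    descriptor = "backbone_N", distance = 2.9, in_plane_angle = 0,
    stringsAsFactors = FALSE), seed = 33L)
  g <- generateSite(plan)
  s <- buildSite(g$structure, matchFragment(g$structure)[[1L]])
  expect_setequal(hbonds(s)$edge,
                  c("watson_crick", "hoogsteen", "sugar"))
})

test_that("planted bonds are recovered exactly over a seed sweep", {
  for (seed in 101:130) {
    g <- generateSite(randomPlan(seed, sigma = 0.1))
    expect_true(recoveredExactly(g), label = paste("seed", seed))
  }
})
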