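test_that("site similarity matches the hand-enumerated mutual-NN result", {
  A <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0))
  s1 <- fakeSite("a", A)
  expect_equal(siteSimilarity(s1, s1)@matchedFraction, 1.0)
  expect_equal(siteSimilarity(s1, s1)@partnerRmsd, 0)

  # 2 of 3 shared within the cutoff -> 2/3, passing the 60% criterion
  B <- rbind(c(0.1, 0, 0), c(5, 0.1, 0), c(9, 9, 0))
  s2 <- fakeSite("b", B)
  sim <- siteSimilarity(s1, s2)
  expect_equal(sim@matchedFraction, 2 / 3, tolerance = 1e-12)
  expect_gt(sim@matchedFraction, 0.6)
  expect_equal(sim@partnerRmsd, 0.1, tolerance = 1e-9)

  # size 3 vs size 5 sharing 3 -> denominator is the larger site
  C <- rbind(A, c(9, 0, 0), c(0, 9, 0))
  s3 <- fakeSite("c", C)
  expect_equal(siteSimilarity(s1, s3)@matchedFraction, 3 / 5)

  # empty site
  s0 <- fakeSite("z", matrix(numeric(), 0L, 3L))
  expect_equal(siteSimilarity(s1, s0)@matchedFraction, 0)
  expect_equal(siteSimilarity(s1, s0)@partnerRmsd, Inf)
})

test_that("similarity is symmetric and respects partner categories", {
  set.seed(42)
  for (k in 1:10) {
    a <- fakeSite("a", matrix(stats::rnorm(12, 0, 2), 4L))
    b <- fakeSite("b", matrix(stats::rnorm(9, 0, 2), 3L))
    sab <- siteSimilarity(a, b); sba <- siteSimilarity(b, a)
    expect_identical(sab@matchedFraction, sba@matchedFraction)
    expect_identical(sab@partnerRmsd, sba@partnerRmsd)
  }
  # same position but different element category never matches
  a <- fakeSite("a", rbind(c(0, 0, 0)), "backbone_N")
  b <- fakeSite("b", rbind(c(0, 0, 0)), "backbone_O")
  expect_equal(siteSimilarity(a, b)@matchedFraction, 0)
  expect_equal(siteSimilarity(a, b, byCategory = FALSE)@matchedFraction, 1)
  # waters are their own category
  w <- fakeSite("w", rbind(c(0, 0, 0)), "water_O")
  expect_equal(siteSimilarity(a, w)@matchedFraction, 0)
})

test_that("network edges honor both thresholds and the node minimum", {
  A <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0))
  shift <- function(d) rbind(A[1, ] + c(d, 0, 0), A[2, ] + c(0, d, 0),
                             c(9, 9, 9))
  s1 <- fakeSite("s1", A)
  s_far <- fakeSite("s2", shift(0.4))   # fraction 2/3, rmsd 0.4
  s_near <- fakeSite("s3", shift(0.2))  # fraction 2/3, rmsd 0.2
  net1 <- buildSiteNetwork(list(s1, s_far))
  expect_equal(igraph::ecount(networkGraph(net1)), 0L)
  net2 <- buildSiteNetwork(list(s1, s_near))
  expect_equal(igraph::ecount(networkGraph(net2)), 1L)

  tiny <- fakeSite("tiny", A[1:2, ])    # 2 hbonds -> excluded from nodes
  net3 <- buildSiteNetwork(list(s1, tiny))
  expect_equal(igraph::vcount(networkGraph(net3)), 1L)

  # identical planted sites connect
  net4 <- buildSiteNetwork(list(s1, fakeSite("dup", A)))
  expect_equal(igraph::ecount(networkGraph(net4)), 1L)
})

test_that("edge sets are monotone under threshold relaxation", {
  set.seed(7)
  sites <- lapply(1:8, function(i)
    fakeSite(sprintf("s%02d", i), matrix(stats::rnorm(9, 0, 1.2), 3L)))
  ekey <- function(net) {
    ed <- igraph::as_data_frame(networkGraph(net), "edges")
    paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  }
  strict <- ekey(buildSiteNetwork(sites, minFraction = 0.9,
                                  maxRmsd = 0.2))
  mid <- ekey(buildSiteNetwork(sites))
  lax <- ekey(buildSiteNetwork(sites, minFraction = 0.3, maxRmsd = 0.8))
  expect_true(all(strict %in% mid))
  expect_true(all(mid %in% lax))
})

test_that("components come back size-ordered and deterministic", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "x"), to = c("b", "c", "y")),
    directed = FALSE,
    vertices = data.frame(name = c("a", "b", "c", "x", "y", "solo")))
  net <- new("FragmentNetwork", graph = g, kind = "site_similarity")
  cc <- connectedComponents(net)
  expect_equal(vapply(cc$components, length, integer(1L)), c(3L, 2L, 1L))
  expect_equal(cc$components[[1L]], c("a", "b", "c"))
  expect_equal(cc$components[[3L]], "solo")
  # 5 singletons -> 5 components
  g5 <- igraph::make_empty_graph(5L, directed = FALSE)
  igraph::V(g5)$name <- letters[1:5]
  cc5 <- connectedComponents(new("FragmentNetwork", graph = g5,
                                 kind = "site_similarity"))
  expect_length(cc5$components, 5L)
})

test_that("family datasets are recovered as components (ARI)", {
  fam <- generateFamilyDataset(3L, 4L, sigmaWithin = 0.05,
                               minBetween = 2.0, seed = 23L)
  sites <- buildAllSites(fam$structures)
  net <- buildSiteNetwork(sites)
  expect_equal(componentsVsFamiliesARI(sites, fam$truth, net), 1.0)

  noisy <- generateFamilyDataset(3L, 4L, sigmaWithin = 1.0,
                                 minBetween = 2.0, seed = 23L)
  nsites <- buildAllSites(noisy$structures)
  nnet <- buildSiteNetwork(nsites)
  expect_lt(componentsVsFamiliesARI(nsites, noisy$truth, nnet), 1.0)
})

test_that("theme participation is required on both endpoints", {
  th <- generateThemeFixture(data.frame(
    complex_id = c("A", "B", "C"), theme_id = 1L,
    covers_binder = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE))
  sites <- buildAllSites(th$structures)
  net <- buildThemeNetwork(sites, th$annotations)
  ed <- igraph::as_data_frame(networkGraph(net), "edges")
  expect_equal(nrow(ed), 1L)
  expect_setequal(sub("\\|.*", "", c(ed$from, ed$to)), c("A", "B"))
  # theme present in both but binding in neither -> empty network
  th0 <- generateThemeFixture(data.frame(
    complex_id = c("A", "B"), theme_id = 1L, covers_binder = FALSE,
    stringsAsFactors = FALSE))
  net0 <- buildThemeNetwork(buildAllSites(th0$structures),
                            th0$annotations)
  expect_equal(igraph::ecount(networkGraph(net0)), 0L)
})

test_that("annotations for unknown complexes are skipped with a warning", {
  th <- generateThemeFixture(data.frame(
    complex_id = c("A", "B"), theme_id = 1L, covers_binder = TRUE,
    stringsAsFactors = FALSE))
  ann <- rbind(th$annotations,
               data.frame(theme_id = 9L, complex_id = "GHOST",
                          chain_id = "A", start = 5L, end = 45L))
  sites <- buildAllSites(th$structures)
  expect_warning(net <- buildThemeNetwork(sites, ann), "GHOST")
  expect_equal(igraph::ecount(networkGraph(net)), 1L)
})

test_that("cluster consensus honors the share threshold exactly", {
  A <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0))
  s1 <- fakeSite("a", A)
  s2 <- fakeSite("b", A + 0.05)
  s3 <- fakeSite("c", A[1:2, ] + 0.02)  # misses the third interaction
  cons_all <- clusterConsensus(list(s1, s2, s3), minShare = 1.0)
  expect_equal(nrow(cons_all), 2L)
  cons_lax <- clusterConsensus(list(s1, s2, s3), minShare = 0.6)
  expect_equal(nrow(cons_lax), 3L)
  expect_true(all(cons_lax$share >= 0.6))
  expect_error(clusterConsensus(list()), "empty")
  expect_error(clusterConsensus(list(s1)), "at least 2")

  # planted reverse-motif cluster: consensus equals the planted bonds
  gs <- lapply(1:3, function(i)
    generateSite(motifPlan("reverse", seed = 600L + i,
                           jitterSigma = 0.05)))
  sites <- lapply(gs, function(g)
    buildSite(g$structure, matchFragment(g$structure)[[1L]]))
  cons <- clusterConsensus(sites, minShare = 1.0)
  expect_equal(nrow(cons), 2L)
  expect_setequal(paste(cons$fragment_atom, cons$descriptor),
                  c("N1 backbone_N", "N6 backbone_O"))
  expect_true(all(cons$spread < 0.2))
})

test_that("fold enrichment reproduces worked arithmetic cases", {
  corpus <- data.frame(
    entry_id = 1:100,
    has_theme = c(rep(TRUE, 10L), rep(FALSE, 90L)),
    has_fragment_ligand = c(rep(TRUE, 5L), rep(FALSE, 5L),
                            rep(TRUE, 5L), rep(FALSE, 85L)))
  e <- themeEnrichment(corpus)
  expect_equal(e@themeFraction, 0.5)
  expect_equal(e@backgroundFraction, 0.1)
  expect_equal(e@fold, 5.0)

  # all theme entries have the ligand, background 0.5 -> fold 2
  corpus2 <- data.frame(entry_id = 1:40,
                        has_theme = rep(c(TRUE, FALSE), each = 20L),
                        has_fragment_ligand = c(rep(TRUE, 20L),
                                                rep(FALSE, 20L)))
  expect_equal(themeEnrichment(corpus2)@fold, 2.0)

  expect_error(themeEnrichment(data.frame(entry_id = 1L,
                                          has_theme = FALSE,
                                          has_fragment_ligand = TRUE)),
               "no theme entries")
})

test_that("independent theme/ligand corpora give fold near 1", {
  set.seed(99)
  n <- 20000L
  corpus <- data.frame(entry_id = seq_len(n),
                       has_theme = stats::runif(n) < 0.3,
                       has_fragment_ligand = stats::runif(n) < 0.1)
  expect_lt(abs(themeEnrichment(corpus)@fold - 1), 0.1)
})

test_that("large-cluster reporting uses the size threshold", {
  mkcomp <- function(prefix, n) {
    if (n == 1L) return(data.frame(from = character(), to = character()))
    data.frame(from = paste0(prefix, seq_len(n - 1L)),
               to = paste0(prefix, 1L + seq_len(n - 1L)))
  }
  ed <- rbind(mkcomp("a", 12L), mkcomp("b", 9L), mkcomp("c", 3L))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  net <- new("FragmentNetwork", graph = g, kind = "site_similarity")
  expect_equal(nrow(reportLargeClusters(net, 10L)), 1L)
  lc <- reportLargeClusters(net, 3L)
  expect_equal(nrow(lc), 3L)
  expect_equal(lc$size, c(12L, 9L, 3L))
})
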