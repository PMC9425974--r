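toyTree <- "((a,b)n1,(c,d)n2)root;"

ppOf <- function(...) {
  PresencePosterior(toyTree, c(...))
}

test_that("discrete events follow the 0.5 posterior-difference rule", {
  # constant presence: exactly one gain, at the root's virtual edge
  pp <- ppOf(a = 1, b = 1, c = 1, d = 1, n1 = 1, n2 = 1, root = 1)
  ev <- inferDiscreteEvents(pp)
  expect_equal(nrow(ev), 1)
  expect_identical(ev$event, "gain")
  expect_true(is.na(ev$parent))
  expect_equal(nrow(inferDiscreteEvents(pp, virtualRoot = FALSE)), 0)

  # a 0.9 -> 0.1 drop is a loss; a 0.6 -> 0.3 drop is no event
  pp2 <- ppOf(a = 0.1, b = 0.9, c = 0.3, d = 0.6, n1 = 0.9, n2 = 0.6,
              root = 0.9)
  ev2 <- inferDiscreteEvents(pp2, virtualRoot = FALSE)
  expect_equal(nrow(ev2), 1)
  expect_identical(ev2$event, "loss")
  expect_identical(ev2$child, which(pp2$tree$tip.label == "a"))

  expect_error(PresencePosterior(toyTree,
    c(a = 1.2, b = 1, c = 1, d = 1, n1 = 1, n2 = 1, root = 1)),
    "lie in")
})

test_that("gain and loss totals are the summed signed posterior differences", {
  # chain root 0 -> mid 1 -> leaf 0
  chain <- PresencePosterior("((x)mid)root;",
                             c(x = 0, mid = 1, root = 0))
  tot <- totalGainsLosses(chain)
  expect_equal(unname(tot["gainTotal"]), 1)
  expect_equal(unname(tot["lossTotal"]), 1)

  # constant posteriors: only the root term contributes
  const <- ppOf(a = 0.7, b = 0.7, c = 0.7, d = 0.7, n1 = 0.7, n2 = 0.7,
                root = 0.7)
  tc <- totalGainsLosses(const)
  expect_equal(unname(tc["gainTotal"]), 0.7)
  expect_equal(unname(tc["gainTotalNoRoot"]), 0)
  expect_equal(unname(tc["lossTotal"]), 0)

  # all-absent family: nothing at all
  zero <- ppOf(a = 0, b = 0, c = 0, d = 0, n1 = 0, n2 = 0, root = 0)
  expect_equal(unname(totalGainsLosses(zero)), c(0, 0, 0, 0))
})

test_that("ancestrality is decided at the root, else by the deepest gain edge", {
  # root exactly at 0.5 counts as ancestral (inclusive threshold)
  pp <- ppOf(a = 0, b = 0, c = 0, d = 0, n1 = 0, n2 = 0, root = 0.5)
  expect_identical(classifyAncestrality(pp)$class, "ancestral")

  # gain on a leaf edge only: terminal acquisition
  ppT <- ppOf(a = 1, b = 0, c = 0, d = 0, n1 = 0, n2 = 0, root = 0.1)
  expect_identical(classifyAncestrality(ppT)$class, "terminal")

  # gain on an internal edge: intermediate acquisition
  ppI <- ppOf(a = 1, b = 1, c = 0, d = 0, n1 = 1, n2 = 0, root = 0.1)
  expect_identical(classifyAncestrality(ppI)$class, "intermediate")

  # internal gain outranks a later terminal gain elsewhere
  ppB <- ppOf(a = 1, b = 1, c = 1, d = 0, n1 = 1, n2 = 0, root = 0.1)
  expect_identical(classifyAncestrality(ppB)$class, "intermediate")

  # no gain anywhere: unclassified
  ppN <- ppOf(a = 0.4, b = 0.4, c = 0.4, d = 0.4, n1 = 0.4, n2 = 0.4,
              root = 0.4)
  expect_identical(classifyAncestrality(ppN)$class, "unclassified")
})

test_that("event inference reproduces simulated binary histories exactly", {
  tree <- ape::read.tree(text = "(((a,b)n1,(c,d)n2)n3,((e,f)n4,g)n5)root;")
  for (s in 1:25) {
    sim <- simulatePresenceHistory(tree, gainRate = 0.25, lossRate = 0.25,
                                   seed = 4000 + s)
    ev <- inferDiscreteEvents(sim$posterior)
    expect_equal(sum(ev$event == "gain"),
                 sum(sim$events$event == "gain"))
    expect_equal(sum(ev$event == "loss"),
                 sum(sim$events$event == "loss"))
    # same edges, not just the same counts
    key <- function(d) sort(paste(d$parent, d$child, d$event))
    expect_identical(key(ev[c("parent", "child", "event")]),
                     key(sim$events))
  }
})

test_that("totals balance presence bookkeeping on binary histories", {
  tree <- ape::read.tree(text = toyTree)
  for (s in 1:10) {
    sim <- simulatePresenceHistory(tree, gainRate = 0.3, lossRate = 0.3,
                                   seed = 6000 + s)
    tot <- totalGainsLosses(sim$posterior)
    ev <- inferDiscreteEvents(sim$posterior)
    # with 0/1 posteriors the summed differences equal the event counts
    expect_equal(unname(tot["gainTotal"]), sum(ev$event == "gain"))
    expect_equal(unname(tot["lossTotal"]), sum(ev$event == "loss"))
  }
})

test_that("totals are invariant under sibling reordering", {
  pp <- ppOf(a = 0.9, b = 0.2, c = 0.8, d = 0.1, n1 = 0.6, n2 = 0.9,
             root = 0.3)
  swapped <- PresencePosterior("((c,d)n2,(b,a)n1)root;",
                               c(a = 0.9, b = 0.2, c = 0.8, d = 0.1,
                                 n1 = 0.6, n2 = 0.9, root = 0.3))
  expect_equal(totalGainsLosses(pp), totalGainsLosses(swapped))
})

test_that("the per-family summary table assembles all statistics", {
  pps <- list(ppOf(a = 1, b = 1, c = 1, d = 1, n1 = 1, n2 = 1, root = 1),
              ppOf(a = 1, b = 0, c = 0, d = 0, n1 = 0, n2 = 0,
                   root = 0.1))
  pps[[1]]$familyId <- "anc"; pps[[2]]$familyId <- "term"
  tab <- gainLossSummary(pps)
  expect_identical(tab$familyId, c("anc", "term"))
  expect_identical(tab$ancestrality, c("ancestral", "terminal"))
  expect_equal(tab$nGains, c(1L, 1L))
})
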