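test_that("mean-shift refinement matches the brute-force update", {
  # two parallel 1-voxel-spaced traces of a radius-2 branch, offset +-1
  xs <- 0:20
  nodes <- data.frame(x = c(xs, xs), y = rep(c(1, -1), each = 21),
                      z = 0, r = 2, c = 0.8)
  ref <- meanShiftRefine(nodes, iterations = 5)
  oracle <- oracleMeanShift(as.matrix(nodes[, c("x", "y", "z")]),
                            nodes$r, nodes$c, 5)
  expect_equal(as.matrix(ref[, c("x", "y", "z")]), oracle$pos,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(ref$r, oracle$r, tolerance = 1e-9)
  # both traces collapse onto the mid-line
  expect_true(all(abs(ref$y) < 0.1))
  # node count unchanged
  expect_equal(nrow(ref), nrow(nodes))
})

test_that("mean-shift fixed points and random-instance agreement", {
  # an isolated node is its own local mean
  one <- data.frame(x = 5, y = 5, z = 5, r = 2, c = 0.5)
  expect_equal(meanShiftRefine(one, 5), one)

  set.seed(31)
  nodes <- data.frame(x = runif(60, 0, 20), y = runif(60, 0, 20),
                      z = runif(60, 0, 6), r = runif(60, 1, 3),
                      c = runif(60))
  ref <- meanShiftRefine(nodes, 3, aspect = c(1, 1, 2))
  oracle <- oracleMeanShift(as.matrix(nodes[, c("x", "y", "z")]),
                            nodes$r, nodes$c, 3, aspect = c(1, 1, 2))
  expect_equal(as.matrix(ref[, c("x", "y", "z")]), oracle$pos,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(ref$c, oracle$c, tolerance = 1e-9)
})

test_that("grouping follows the greedy highest-correlation order", {
  # worked 3-node chain: seeded at c = 0.9, all within rg = 2
  nodes <- data.frame(x = c(0, 1, 2), y = 0, z = 0, r = 1,
                      c = c(0.9, 0.8, 0.7))
  g <- groupNodes(nodes, matrix(integer(0), ncol = 2), rg = 2)
  expect_equal(nrow(g$nodes), 1)
  expect_equal(g$nodes$x, 1)
  expect_equal(g$nodes$c, 0.8)
  expect_equal(g$nodes$size, 3)

  # far-apart nodes each form their own group with copied fields
  far <- data.frame(x = c(0, 10, 20), y = 0, z = 0, r = 1,
                    c = c(0.5, 0.9, 0.7))
  g2 <- groupNodes(far, matrix(integer(0), ncol = 2), rg = 2)
  expect_equal(nrow(g2$nodes), 3)
  expect_setequal(g2$nodes$x, c(0, 10, 20))

  # random instances match the independent greedy oracle
  set.seed(41)
  for (k in 1:20) {
    n <- 30
    nd <- data.frame(x = runif(n, 0, 15), y = runif(n, 0, 15),
                     z = runif(n, 0, 5), r = 1, c = runif(n))
    got <- groupNodes(nd, matrix(integer(0), ncol = 2), rg = 2)
    want <- oracleGroup(as.matrix(nd[, c("x", "y", "z")]), nd$c, 2)
    expect_equal(got$membership, want)
    # partition: every node in exactly one group
    expect_equal(sum(got$nodes$size), n)
    expect_lte(nrow(got$nodes), n)
  }
})

test_that("grouping projects links onto the group graph", {
  # chain a - b - c where a, b merge and c stays separate
  nodes <- data.frame(x = c(0, 1, 5), y = 0, z = 0, r = 1,
                      c = c(0.9, 0.8, 0.7))
  edges <- rbind(c(1L, 2L), c(2L, 3L))
  g <- groupNodes(nodes, edges, rg = 2)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  ga <- g$membership[1]
  gc <- g$membership[3]
  expect_setequal(as.integer(g$edges[1, ]), c(ga, gc))
  # intra-group links vanish, connectivity across groups is preserved
})

test_that("tree construction roots, traverses, and prunes correctly", {
  # linear chain of 5 groups, no soma: path rooted at the max-c node
  nodes <- data.frame(x = 0:4, y = 0, z = 0, r = 1,
                      c = c(0.5, 0.6, 0.9, 0.6, 0.5), size = 1L)
  edges <- cbind(1:4, 2:5)
  groups <- list(nodes = nodes, edges = edges)
  tree <- buildTree(groups, SomaModel(), c(1, 1, 1), prune = FALSE)
  nd <- swcNodes(tree)
  expect_equal(nrow(nd), 5)
  expect_equal(sum(nd$parent == -1), 1)
  expect_equal(nd$x[1], 2)  # root at the highest correlation
  expect_true(all(nd$parent[-1] %in% nd$id))

  # a 4-cycle becomes a 4-node spanning tree with 3 edges
  sq <- list(nodes = data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1),
                                z = 0, r = 1, c = c(0.9, 0.5, 0.5, 0.5),
                                size = 1L),
             edges = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L)))
  sqTree <- buildTree(sq, SomaModel(), c(1, 1, 1), prune = FALSE)
  snd <- swcNodes(sqTree)
  expect_equal(nrow(snd), 4)
  expect_equal(sum(snd$parent > 0), 3)
  expect_equal(sum(snd$parent == -1), 1)

  # an isolated single group far from the root is discarded
  iso <- list(nodes = rbind(nodes,
                            data.frame(x = 50, y = 50, z = 0, r = 1,
                                       c = 0.4, size = 1L)),
              edges = edges)
  isoTree <- buildTree(iso, SomaModel(), c(1, 1, 1), minComponent = 3,
                       prune = FALSE)
  expect_equal(nNodes(isoTree), 5)

  # single-node terminal twigs are pruned
  spur <- list(nodes = rbind(nodes,
                             data.frame(x = 2, y = 1, z = 0, r = 1,
                                        c = 0.3, size = 1L)),
               edges = rbind(edges, c(3L, 6L)))
  spurTree <- buildTree(spur, SomaModel(), c(1, 1, 1), prune = TRUE)
  expect_equal(nNodes(spurTree), 5)
  noPrune <- buildTree(spur, SomaModel(), c(1, 1, 1), prune = FALSE)
  expect_equal(nNodes(noPrune), 6)
})

test_that("a found soma becomes the type-1 root of the tree", {
  nodes <- data.frame(x = c(10, 13, 16), y = 0, z = 0, r = 1,
                      c = c(0.9, 0.8, 0.7), size = 1L)
  edges <- cbind(1:2, 2:3)
  soma <- SomaModel(center = c(5, 0, 0), radius = 5, found = TRUE)
  tree <- buildTree(list(nodes = nodes, edges = edges), soma, c(1, 1, 1),
                    prune = FALSE)
  nd <- swcNodes(tree)
  expect_equal(nd$type[1], 1L)
  expect_equal(nd$parent[1], -1L)
  expect_equal(nd$x[1], 5)
  # the group within soma radius + its own radius attaches to the root
  expect_equal(nd$parent[nd$x == 10], 1L)
  expect_equal(sum(nd$parent == -1), 1)
})

test_that("end-to-end reconstruction recovers the Y topology", {
  vol <- simulateY(snr = 20, seed = 55)
  cfg <- reconstructionConfig(voxelAspect = c(1, 1, 1), seed = 7)
  tree <- reconstructNeuron(vol, cfg)
  expect_gt(nNodes(tree), 10)
  nd <- swcNodes(tree)
  children <- tabulate(nd$parent[nd$parent > 0], nrow(nd))
  deg <- children + (nd$parent != -1)
  expect_gte(sum(deg >= 3), 1)   # at least the bifurcation
  expect_gte(sum(deg == 1), 3)   # three terminals
  sc <- scoreReconstruction(tree, yPhantom(), 2, c(1, 1, 1))
  expect_gt(sc$f, 0.8)

  # determinism: identical runs give identical trees
  tree2 <- reconstructNeuron(vol, cfg)
  expect_identical(swcNodes(tree), swcNodes(tree2))
})

test_that("pure background yields an empty or tiny reconstruction", {
  set.seed(67)
  noise <- IntensityVolume(array(rpois(48 * 48 * 16, 10), c(48, 48, 16)),
                           c(1, 1, 1))
  cfg <- reconstructionConfig(voxelAspect = c(1, 1, 1), seed = 5)
  tree <- suppressWarnings(reconstructNeuron(noise, cfg))
  expect_lt(nNodes(tree), 10)
})
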