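test_that("delay matrix equals pairwise distance over velocity", {
  atlas <- small_head()$atlas
  D <- build_delay_matrix(atlas, velocity = 7.5)
  expect_true(isSymmetric(unname(D)))
  expect_identical(unname(diag(D)), rep(0, nrow(atlas)))
  # 75 mm at 7.5 m/s -> 10 ms
  a2 <- brain_atlas(data.frame(name = c("a", "b"), hemisphere = "lh",
                               x = c(0, 75), y = 0, z = 0))
  expect_equal(build_delay_matrix(a2, 7.5)["a", "b"], 0.010)
  # identical centroids -> zero delay
  a3 <- brain_atlas(data.frame(name = c("a", "b"), hemisphere = "lh",
                               x = 1, y = 2, z = 3))
  expect_identical(max(build_delay_matrix(a3, 7.5)), 0)
  expect_error(build_delay_matrix(atlas, 0), "velocity")
  # random 5-region atlas vs element-wise recomputation
  set.seed(42)
  a5 <- brain_atlas(data.frame(name = letters[1:5], hemisphere = "lh",
                               x = runif(5, -50, 50), y = runif(5, -50, 50),
                               z = runif(5, -50, 50)))
  D5 <- build_delay_matrix(a5, 3.1)
  for (i in 1:5) for (j in 1:5) {
    d_mm <- sqrt(sum((as.numeric(a5[i, c("x", "y", "z")]) -
                        as.numeric(a5[j, c("x", "y", "z")]))^2))
    expect_equal(D5[i, j], d_mm / 1000 / 3.1, tolerance = 1e-12)
  }
})

test_that("default network has 67 masses, 66 cortical", {
  model <- small_model()
  expect_identical(n_masses(model), 67L)
  expect_length(model$regions, 66L)
  expect_false("Thalamus" %in% model$regions)
  expect_error(build_network(small_head()$atlas, small_conn()[1:10, 1:10]),
               "match")
})

test_that("decoupled network equals isolated columns exactly (shared noise streams)", {
  head <- make_synthetic_head(n_regions = 4, n_electrodes = 8, seed = 2)
  atlas_nothal <- brain_atlas(as.data.frame(
    head$atlas[head$atlas$name != "Thalamus", ]))
  conn0 <- matrix(0, 4, 4, dimnames = list(atlas_nothal$name, atlas_nothal$name))
  model <- build_network(atlas_nothal, conn0, global_coupling = 0)
  net <- simulate_network(model, duration = 3, seed = 50)
  for (i in 1:4) {
    col <- simulate_column(cortical_column_params(), duration = 3,
                           seed = 50 + i - 1, record_pops = FALSE)
    expect_identical(unname(net[, i]), col$lfp)
  }
})

test_that("fragmentation keeps the parental connectivity and the rest bit-identical", {
  head <- small_head()
  conn <- small_conn()
  fr <- fragment_region(head$atlas, conn, "lh_rostralmiddlefrontal",
                        c(1 / 3, 1 / 3, 1 / 3))
  kids <- paste0("lh_rostralmiddlefrontal_f", 1:3)
  expect_true(all(kids %in% fr$atlas$name))
  expect_false("lh_rostralmiddlefrontal" %in% fr$atlas$name)
  expect_identical(fr$atlas$parent[fr$atlas$name %in% kids], rep("lh_rostralmiddlefrontal", 3))
  others <- setdiff(rownames(conn), "lh_rostralmiddlefrontal")
  for (k in kids) {
    expect_identical(unname(fr$connectivity[k, others]),
                     unname(conn["lh_rostralmiddlefrontal", others]))
    expect_identical(unname(fr$connectivity[others, k]),
                     unname(conn[others, "lh_rostralmiddlefrontal"]))
  }
  # all other entries untouched, bit-identical
  expect_identical(fr$connectivity[others, others], conn[others, others])
  # children's extents sum to the parent's (surface bookkeeping)
  i <- match("lh_rostralmiddlefrontal", head$atlas$name)
  expect_equal(sum(fr$atlas$extent[fr$atlas$name %in% kids]),
               head$atlas$extent[i])
  # children stay on the parent's cortical shell
  r_parent <- sqrt(sum(head$atlas[i, c("x", "y", "z")]^2))
  for (k in kids) {
    j <- match(k, fr$atlas$name)
    expect_equal(sqrt(sum(fr$atlas[j, c("x", "y", "z")]^2)), r_parent,
                 tolerance = 1e-9)
  }
  # fragment into one part: connectivity unchanged up to renaming
  fr1 <- fragment_region(head$atlas, conn, "lh_cuneus", 1)
  expect_true("lh_cuneus_f1" %in% rownames(fr1$connectivity))
  m <- fr1$connectivity
  rownames(m)[rownames(m) == "lh_cuneus_f1"] <- "lh_cuneus"
  colnames(m)[colnames(m) == "lh_cuneus_f1"] <- "lh_cuneus"
  expect_equal(m[rownames(conn), colnames(conn)], conn)
  expect_error(fragment_region(head$atlas, conn, "nope", 1), "unknown")
  expect_error(fragment_region(head$atlas, conn, "lh_cuneus", c(0.5, 0.4)),
               "summing to 1")
})

test_that("annulment zeroes exactly the region's row and column", {
  m <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  a <- annul_region_connections(m, "b")
  expect_identical(unname(a["b", ]), rep(0, 4))
  expect_identical(unname(a[, "b"]), rep(0, 4))
  # exactly 2*(4-1) weights changed
  expect_identical(sum(m != a), 6L)
  # annulling an isolated region changes nothing
  expect_identical(annul_region_connections(a, "b"), a)
  # annulling all regions gives the zero matrix
  z <- annul_region_connections(m, letters[1:4])
  expect_identical(max(z), 0)
  expect_error(annul_region_connections(m, "x"), "unknown")
  # fragment then annul one child: only that child zeroed
  fr <- fragment_region(small_head()$atlas, small_conn(),
                        "lh_rostralmiddlefrontal", c(0.5, 0.5))
  ann <- annul_region_connections(fr$connectivity, "lh_rostralmiddlefrontal_f1")
  expect_identical(max(abs(ann["lh_rostralmiddlefrontal_f1", ])), 0)
  keep <- setdiff(rownames(ann), "lh_rostralmiddlefrontal_f1")
  expect_identical(ann[keep, keep], fr$connectivity[keep, keep])
})

test_that("EZ transients localize to the EZ and its strongest afferent targets", {
  model <- small_model()
  ez <- "lh_rostralmiddlefrontal"
  tr <- simulate_network(model, duration = 12, seed = 1, ez_regions = ez)
  fs <- attr(tr, "fs")
  counts <- vapply(colnames(tr), function(r) count_complexes(tr[, r], fs),
                   integer(1))
  expect_gt(counts[ez], 12 * 2 * 0.8) # the EZ itself discharges at ~2-3/s
  expect_identical(sum(counts[setdiff(names(counts), ez)]), 0L)
  # attenuated propagation: with the identical noise streams, switching the
  # EZ on perturbs its strongest afferent targets far more than regions it
  # does not project to (the response stays sub-threshold, i.e. attenuated)
  tr0 <- simulate_network(model, duration = 12, seed = 1)
  w <- model$connectivity[ez, ]
  strong <- names(sort(w, decreasing = TRUE))[1:3]
  weak <- names(w[w == 0])[1:3]
  impact <- vapply(c(strong, weak), function(r) sqrt(mean((tr[, r] - tr0[, r])^2)),
                   numeric(1))
  expect_gt(min(impact[1:3]), 0) # the EZ output does reach its targets
  expect_gt(mean(impact[1:3]), 2 * mean(impact[4:6]))
  expect_identical(sum(vapply(strong, function(r)
    count_complexes(tr[, r], fs), integer(1))), 0L)
})

test_that("all-background network shows no spike-wave transients anywhere", {
  model <- small_model()
  tr <- simulate_network(model, duration = 12, seed = 2)
  fs <- attr(tr, "fs")
  counts <- vapply(colnames(tr), function(r) count_complexes(tr[, r], fs),
                   integer(1))
  expect_identical(sum(counts), 0L)
})

test_that("network simulation is deterministic and validates inputs", {
  model <- small_model()
  a <- simulate_network(model, duration = 2, seed = 3)
  b <- simulate_network(model, duration = 2, seed = 3)
  expect_identical(unclass(a)[, ], unclass(b)[, ])
  expect_error(simulate_network(model, duration = 2, seed = 1,
                                ez_regions = "nowhere"), "unknown EZ")
})
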