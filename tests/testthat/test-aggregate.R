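test_that("region unions and the IDR/DtO split follow the at-least-once rule", {
  cl <- fake_cluster(list(
    list(missing = 1:5, soft = list("1" = c(10, 11)), interface = 20:25),
    list(missing = 3:7, soft = list("1" = c(11, 12)), interface = 20:30)
  ), L = 50)
  un <- region_unions(cl)
  expect_equal(un$UMR, 1:7)
  expect_equal(un$IDR, 3:5)
  expect_equal(un$DtO, c(1, 2, 6, 7))
  expect_equal(un$USDR[["1"]], 10:12)
  expect_equal(un$UIR, 20:30)
})

test_that("a single-member cluster has no DtO and IDR equals its missing set", {
  cl <- fake_cluster(list(list(missing = 4:9)), L = 30)
  un <- region_unions(cl)
  expect_equal(un$DtO, integer(0))
  expect_equal(un$IDR, 4:9)
})

test_that("UMR is the disjoint union of IDR and DtO on random clusters", {
  withr::with_seed(41, {
    for (i in 1:20) {
      L <- sample(40:120, 1)
      members <- lapply(seq_len(sample(2:6, 1)), function(m) {
        list(missing = sort(sample(L, sample(0:10, 1))),
             covered = sort(sample(L, round(0.9 * L))))
      })
      un <- region_unions(fake_cluster(members, L))
      expect_setequal(union(un$IDR, un$DtO), un$UMR)
      expect_length(intersect(un$IDR, un$DtO), 0L)
    }
  })
})

test_that("NDI counts interfaces distinct beyond 5% of the reference length", {
  # concentric but significantly larger interfaces are different
  cl <- fake_cluster(list(list(interface = 1:10), list(interface = 1:30)),
                     L = 100)
  nd <- count_ndi(cl)
  expect_equal(nd$ndi, 2L)

  cl2 <- fake_cluster(list(
    list(interface = 1:10),
    list(interface = c(1:10, 50:60)),
    list(interface = 2:10)
  ), L = 200)
  expect_equal(count_ndi(cl2)$ndi, 2L)

  shared <- fake_cluster(lapply(1:4, function(i) list(interface = 5:15)),
                         L = 100)
  expect_equal(count_ndi(shared)$ndi, 1L)

  unbound <- fake_cluster(list(list(missing = 1:3)), L = 100)
  expect_equal(count_ndi(unbound)$ndi, 0L)
})

test_that("NDI is invariant under member duplication and bounded by bound members", {
  withr::with_seed(42, {
    for (i in 1:10) {
      L <- 150
      members <- lapply(seq_len(sample(2:6, 1)), function(m) {
        s <- sample(L - 20, 1)
        list(interface = s:(s + sample(5:20, 1)))
      })
      cl <- fake_cluster(members, L)
      nd <- count_ndi(cl)
      dup <- fake_cluster(c(members, members[sample(length(members), 1)]), L)
      expect_equal(count_ndi(dup)$ndi, nd$ndi)
      expect_lte(nd$ndi, length(members))
    }
  })
})

test_that("nested interfaces form a transitively reduced containment chain", {
  sets <- list(a = 1:10, b = 1:20, c = 1:30)
  g <- interface_hierarchy(sets, L_ref = 200)
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 2L)
  expect_equal(el[order(el[, 1]), ], rbind(c("a", "b"), c("b", "c")))
  expect_true(igraph::is_dag(g))

  disj <- interface_hierarchy(list(a = 1:10, b = 50:60), L_ref = 100)
  expect_equal(igraph::ecount(disj), 0L)

  single <- interface_hierarchy(list(a = 1:10), L_ref = 100)
  expect_equal(igraph::vcount(single), 1L)
  expect_equal(igraph::ecount(single), 0L)
})

test_that("hierarchy edges always point from smaller to larger interfaces", {
  withr::with_seed(43, {
    for (i in 1:10) {
      L <- 200
      sets <- lapply(1:4, function(k) {
        s <- sample(100, 1)
        s:(s + sample(10:60, 1))
      })
      names(sets) <- paste0("s", 1:4)
      g <- interface_hierarchy(sets, L)
      el <- igraph::as_edgelist(g)
      if (nrow(el)) {
        tol <- 0.05 * L
        for (e in seq_len(nrow(el))) {
          A <- sets[[el[e, 1]]]
          B <- sets[[el[e, 2]]]
          expect_lt(length(A), length(B) + tol)
        }
      }
      expect_true(igraph::is_dag(g))
    }
  })
})

test_that("connected regions use single-linkage at 6 A on the reference trace", {
  ch <- straight_chain("t", "A", rep("A", 60))
  expect_equal(connected_regions(integer(0), ch), 0L)
  # 1..3 linked through 2 even though d(1,3) = 7.6 > 6
  expect_equal(connected_regions(1:3, ch), 1L)
  expect_equal(connected_regions(c(1:3, 50:51), ch), 2L)
  # positions without coordinates are skipped
  ch2 <- straight_chain("t", "A", rep("A", 30), missing_pos = 5:6)
  expect_equal(connected_regions(4:7, ch2), 2L)
})

test_that("connected regions agree with a breadth-first-search oracle", {
  withr::with_seed(44, {
    for (i in 1:10) {
      L <- 80
      xyz <- softdis:::.saw_trace(L)
      ch <- softdis:::.make_protein_chain("t", "A",
                                          sample(softdis:::.AA20, L, TRUE),
                                          xyz, rep(30, L), integer(0))
      pos <- sort(sample(L, sample(5:30, 1)))
      expect_equal(connected_regions(pos, ch),
                   bfs_components(xyz[pos, , drop = FALSE], 6.0))
    }
  })
})

test_that("DtO interface frequencies count only structured occurrences", {
  # position 10: structured in 4 members, interface in 1 of them
  members <- c(
    list(list(missing = 10L)),
    lapply(1:4, function(i)
      list(interface = if (i == 1) c(10L, 20L) else 20:21))
  )
  cl <- fake_cluster(members, L = 30)
  un <- region_unions(cl)
  expect_true(10L %in% un$DtO)
  fr <- dto_interface_frequencies(cl, un$DtO)
  expect_equal(unname(fr$freq[["10"]]), 0.25)

  # never interface -> 0; always interface when structured -> 1
  members2 <- list(
    list(missing = c(5L, 6L)),
    list(interface = c(6L, 7L)),
    list(interface = c(6L, 7L))
  )
  cl2 <- fake_cluster(members2, L = 30)
  fr2 <- dto_interface_frequencies(cl2)
  expect_equal(unname(fr2$freq[["5"]]), 0)
  expect_equal(unname(fr2$freq[["6"]]), 1)
  expect_equal(fr2$frac_majority, 0.5)
})

test_that("unbound USDR unions soft sets over unbound members only", {
  cl <- fake_cluster(list(
    list(soft = list("1" = c(3L, 4L))),
    list(soft = list("1" = c(4L, 5L)), interface = 20:25)
  ), L = 40)
  u <- unbound_usdr(cl, 1)
  expect_true(u$present)
  expect_equal(u$positions, c(3L, 4L))
  expect_true(all(u$positions %in% region_unions(cl)$USDR[["1"]]))

  allbound <- fake_cluster(list(list(interface = 1:10)), L = 40)
  u2 <- unbound_usdr(allbound, 1)
  expect_false(u2$present)
  expect_equal(u2$positions, integer(0))
})

test_that("summarize_cluster ties the pieces together on a planted cluster", {
  gen <- generate_cluster(synthetic_spec(seed = 45))
  cl <- cluster_from_synthetic(gen)
  s <- summarize_cluster(cl)
  expect_equal(s$NDI, gen$truth$ndi)
  expect_equal(s$L_ref, gen$spec$L)
  expect_setequal(union(s$IDR, s$DtO), s$UMR)
  expect_true(all(gen$truth$interfaces[[gen$truth$ndi]] %in% s$UIR))
  expect_gte(s$n_regions_UIR, 1L)
  el <- igraph::as_edgelist(s$hierarchy)
  expect_equal(nrow(el), gen$truth$ndi - 1L)
})
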