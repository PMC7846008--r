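test_that("normalized b-factors use the per-chain population z-score", {
  ch <- straight_chain("t", "A", c("A", "G", "S"), B = c(10, 20, 30))
  b <- normalized_bfactor(ch)
  expect_equal(b, c(-1.224745, 0, 1.224745), tolerance = 1e-6)

  const <- straight_chain("t", "A", c("A", "G", "S"), B = c(7, 7, 7))
  expect_equal(normalized_bfactor(const), c(0, 0, 0))

  nob <- straight_chain("t", "A", c("A", "G", "S"), missing_pos = 1:3)
  expect_error(normalized_bfactor(nob), "annotation error")
})

test_that("normalization forces mean 0 and unit spread on random chains", {
  withr::with_seed(21, {
    for (i in 1:20) {
      L <- sample(20:200, 1)
      miss <- sample(c(0, 2), 1)
      ch <- straight_chain("t", "A", sample(softdis:::.AA20, L, TRUE),
                           B = runif(L, 5, 80),
                           missing_pos = if (miss) sample(L, miss) else integer(0))
      b <- normalized_bfactor(ch)
      obs <- b[!is.na(b)]
      expect_lt(abs(mean(obs)), 1e-9)
      expect_lt(abs(sqrt(mean((obs - mean(obs))^2)) - 1), 1e-9)
      expect_true(all(is.na(b[ch$residues$is_missing])))
    }
  })
})

test_that("soft-disorder sets respect thresholds and are monotone in theta", {
  b <- c(-1.22, 0, 1.22)
  expect_equal(soft_disorder_flags(b, 1), 3L)
  expect_equal(soft_disorder_flags(rep(0, 5), 1), integer(0))
  withr::with_seed(22, {
    for (i in 1:10) {
      b <- rnorm(100)
      s05 <- soft_disorder_flags(b, 0.5)
      s1 <- soft_disorder_flags(b, 1)
      s2 <- soft_disorder_flags(b, 2)
      s3 <- soft_disorder_flags(b, 3)
      expect_true(all(s3 %in% s2) && all(s2 %in% s1) && all(s1 %in% s05))
    }
  })
  # static absolute-B variant
  expect_equal(soft_disorder_flags(b = NULL, B = c(10, 50, 70), static_b = 50),
               2:3)
})

test_that("Calpha contacts use an inclusive 5 A cutoff", {
  a <- straight_chain("t", "A", c("A", "G"))
  near <- straight_chain("t", "B", c("G", "G"), offset = c(0, 4.9, 0))
  far <- straight_chain("t", "B", c("G", "G"), offset = c(0, 5.1, 0))
  vfar <- straight_chain("t", "B", rep("G", 10), offset = c(0, 100, 0))
  expect_equal(protein_protein_interface(a, near), 1:2)
  expect_equal(protein_protein_interface(a, far), integer(0))
  expect_equal(protein_protein_interface(a, vfar), integer(0))
  at5 <- straight_chain("t", "B", c("G", "G"), offset = c(0, 5.0, 0))
  expect_equal(protein_protein_interface(a, at5), 1:2)
})

test_that("contact detection is symmetric between the two chains", {
  withr::with_seed(23, {
    for (i in 1:5) {
      xa <- softdis:::.saw_trace(30)
      xb <- sweep(softdis:::.saw_trace(25), 2L, c(6, 2, 0), `+`)
      a <- softdis:::.make_protein_chain("t", "A",
                                         sample(softdis:::.AA20, 30, TRUE),
                                         xa, rep(30, 30), integer(0))
      b <- softdis:::.make_protein_chain("t", "B",
                                         sample(softdis:::.AA20, 25, TRUE),
                                         xb, rep(30, 25), integer(0))
      ia <- protein_protein_interface(a, b)
      ib <- protein_protein_interface(b, a)
      expect_equal(length(ia) > 0L, length(ib) > 0L)
    }
  })
})

test_that("sasa matches the closed form for one atom and vanishes when buried", {
  one <- data.frame(x = 0, y = 0, z = 0, element = "C", group = "r1")
  expect_equal(sasa(one), c(r1 = 4 * pi * (1.7 + 1.4)^2), tolerance = 1e-3)

  # bury the atom in a 3x3x3 grid of carbons
  g <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2))
  shell <- data.frame(g, element = "C",
                      group = ifelse(g$x == 0 & g$y == 0 & g$z == 0,
                                     "core", "shell"))
  a <- sasa(shell)
  expect_lt(a[["core"]], 1)
})

test_that("adding partner atoms can only decrease per-residue sasa", {
  withr::with_seed(24, {
    xa <- softdis:::.saw_trace(25)
    prot <- data.frame(x = xa[, 1], y = xa[, 2], z = xa[, 3], element = "C",
                       group = as.character(1:25))
    part <- data.frame(x = xa[1:8, 1], y = xa[1:8, 2] + 4.2, z = xa[1:8, 3],
                       element = "C", group = "p")
    alone <- sasa(prot)
    cplx <- sasa(rbind(prot, part))[names(alone)]
    expect_true(all(cplx <= alone + 1e-9))
  })
})

test_that("nucleic interfaces come from surface-area decrease against DNA partners", {
  gen <- generate_cluster(synthetic_spec(n_interfaces = 1, seed = 3,
                                         partner_type = "dna"))
  e <- gen$entries[[2]]
  planted <- gen$truth$members[[2]]$interface
  got <- nucleic_interface(e$chains$A, e)
  expect_true(all(planted %in% got))
  far <- setdiff(seq_len(gen$spec$L), (min(planted) - 5):(max(planted) + 5))
  expect_length(intersect(got, far), 0L)

  no_nuc <- gen$entries[[1]]
  expect_equal(nucleic_interface(no_nuc$chains$A, no_nuc), integer(0))
})

test_that("annotate_chain assembles interfaces, partners and the bound flag", {
  withr::with_seed(25, {
    solo <- fake_entry(list(straight_chain("s1", "A",
                                           sample(softdis:::.AA20, 30, TRUE),
                                           B = runif(30, 10, 60))),
                       entry_id = "s1")
  })
  ann <- annotate_chain(solo, solo$chains$A)
  expect_false(ann$bound)
  expect_equal(ann$interface, integer(0))
  expect_equal(ann$partner_count, 0L)

  gen <- generate_cluster(synthetic_spec(seed = 7))
  e <- gen$entries[[2]]
  ann2 <- annotate_chain(e, e$chains$A)
  expect_true(ann2$bound)
  expect_equal(ann2$partner_count, 1L)
  expect_equal(ann2$interface, gen$truth$members[[2]]$interface)
  # soft sets are monotone and exclude missing positions
  expect_true(all(ann2$soft[["2"]] %in% ann2$soft[["1"]]))
  expect_length(intersect(ann2$soft[["0.5"]], ann2$missing), 0L)
})

test_that("a protein partner and a DNA partner contribute separate interface keys", {
  withr::with_seed(26, {
    L <- 40
    xa <- cbind(3.8 * (seq_len(L) - 1), 0, 0)
    a <- softdis:::.make_protein_chain("mx", "A",
                                       sample(softdis:::.AA20, L, TRUE),
                                       xa, runif(L, 10, 60), integer(0))
    # protein partner near residues 5:8, DNA partner near residues 30:33
    bpts <- cbind(xa[5:8, 1], 4.5, 0)
    b <- softdis:::.make_partner_chain("mx", "B", bpts, "protein")
    cpts <- cbind(xa[30:33, 1], 4.0, 0)
    cc <- softdis:::.make_partner_chain("mx", "C", cpts, "dna")
    e <- fake_entry(list(a, b, cc), entry_id = "mx")
  })
  ann <- annotate_chain(e, e$chains$A)
  expect_setequal(names(ann$interface_by_partner), c("B", "C"))
  expect_true(all(5:8 %in% ann$interface_by_partner$B))
  expect_true(all(30:33 %in% ann$interface_by_partner$C))
  expect_equal(ann$partner_count, 2L)
})
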