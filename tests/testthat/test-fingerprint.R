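test_that("fingerprint_length evaluates both conventions", {
  expect_identical(fingerprint_length(10, "positive-only"), 30226L)
  expect_identical(fingerprint_length(10, "inclusive-zero"), 44191L)
  expect_identical(fingerprint_length(1), 64L)
  expect_error(fingerprint_length(0), ">= 1")
})

test_that("index_of places the section-3 anchors correctly", {
  for (m in c(2L, 5L, 10L)) {
    # O(0,0) opens section 3; O(0,MAX) closes its first row (1-based here)
    expect_identical(index_of("O(0,0)", m), 6L + 2L * m + 1L)
    expect_identical(index_of(sprintf("O(0,%d)", m), m), 6L + 2L * m + m + 1L)
  }
  expect_error(index_of("O(3)", 2), "out of range")
  expect_error(index_of("O(0,5)", 2), "out of range")
})

test_that("labels tile each section exactly and label_of inverts index_of", {
  for (m in 1:3) {
    w <- m + 1L
    labels <- c(
      sprintf("O(%d)", 1:m), sprintf("M(%d)", 1:m),
      c(outer(0:m, 0:m, function(x, y) sprintf("O(%d,%d)", x, y))),
      c(outer(0:m, 0:m, function(x, y) sprintf("M(%d,%d)", x, y)))
    )
    # symmetric pair labels, canonical order only; O-M over the full grid
    envs <- expand.grid(x = 0:m, y = 0:m)
    p <- envs$x * w + envs$y
    same <- expand.grid(i = seq_len(w^2), j = seq_len(w^2))
    same <- same[p[same$i] <= p[same$j], ]
    oo <- sprintf("O(%d,%d)-O(%d,%d)", envs$x[same$i], envs$y[same$i],
                  envs$x[same$j], envs$y[same$j])
    mm <- sprintf("M(%d,%d)-M(%d,%d)", envs$x[same$i], envs$y[same$i],
                  envs$x[same$j], envs$y[same$j])
    om_grid <- expand.grid(i = seq_len(w^2), j = seq_len(w^2))
    om <- sprintf("O(%d,%d)-M(%d,%d)", envs$x[om_grid$i], envs$y[om_grid$i],
                  envs$x[om_grid$j], envs$y[om_grid$j])
    labels <- c(labels, oo, mm, om)

    pos <- index_of(labels, m)
    expect_false(anyDuplicated(pos) > 0)
    expect_true(all(pos >= 7L & pos <= fingerprint_length(m)))
    # canonical labels cover every slot not aliased by symmetry
    w4 <- w^4
    n_sym <- w^2 * (w^2 + 1) / 2
    expect_identical(length(pos), as.integer(2 * m + 2 * w^2 + 2 * n_sym + w4))
    # round-trip through label_of on the canonical slots
    expect_identical(index_of(label_of(pos, m), m), pos)
  }
})

test_that("symmetric pair labels canonicalise to one slot", {
  expect_identical(index_of("O(0,1)-O(1,0)", 3), index_of("O(1,0)-O(0,1)", 3))
  expect_identical(index_of("M(2,1)-M(0,3)", 3), index_of("M(0,3)-M(2,1)", 3))
  # mixed pairs: the oxygen environment indexes the row regardless of order
  expect_identical(index_of("M(2,0)-O(0,1)", 3), index_of("O(0,1)-M(2,0)", 3))
})

test_that("hand-enumerated fingerprints: diatomic and linear molecules", {
  dia <- nano_structure(c("O", "Ti"), rbind(c(0, 0, 0), c(1.95, 0, 0)))
  fp <- build_fingerprint(dia, thickness = compute_size(dia), max_bonds = 2)
  expect_equal(fp_count(fp, c("O(1)", "M(1)", "O(0,1)", "M(1,0)", "O(0,1)-M(1,0)")),
               c(1, 1, 1, 1, 1))
  expect_equal(sum(fp$vector[-(1:6)]), 5)  # nothing else is counted
  expect_identical(fp$n_O_shell, 1L)
  expect_identical(fp$n_M_shell, 1L)
  expect_identical(fp$metal_atomic_number, 22L)

  lin <- nano_structure(c("O", "Ti", "O"),
                        rbind(c(-1.95, 0, 0), c(0, 0, 0), c(1.95, 0, 0)))
  fp2 <- build_fingerprint(lin, thickness = compute_size(lin), max_bonds = 2)
  expect_equal(fp_count(fp2, c("M(2)", "O(1)", "M(2,0)", "O(0,1)", "O(0,1)-M(2,0)")),
               c(1, 2, 1, 2, 2))
  expect_equal(sum(fp2$vector[-(1:6)]), 8)
})

test_that("built vector length always matches the closed form", {
  dia <- nano_structure(c("O", "Ti"), rbind(c(0, 0, 0), c(1.95, 0, 0)))
  for (m in c(1L, 3L, 7L)) {
    fp <- build_fingerprint(dia, thickness = 2, max_bonds = m)
    expect_identical(length(fp$vector), as.integer(fingerprint_length(m)))
  }
})

test_that("atoms above MAX are excluded from counting sections but not slots 5/6", {
  # central Ti bonded to 4 O; MAX=3 drops the Ti and its bonds
  co <- rbind(c(0, 0, 0), c(1.95, 0, 0), c(-1.95, 0, 0), c(0, 1.95, 0), c(0, -1.95, 0))
  s <- nano_structure(c("Ti", rep("O", 4)), co)
  fp <- build_fingerprint(s, thickness = compute_size(s), max_bonds = 3)
  expect_identical(fp$n_M_shell, 1L)                # still present in the shell
  pos <- fp_section_positions(3)
  expect_equal(sum(fp$vector[pos$s2_M]), 0)         # but not counted
  expect_equal(sum(fp$vector[c(pos$s4_OO, pos$s4_MM, pos$s4_OM)]), 0)
  # the oxygens keep their own environment counts
  expect_equal(fp_count(fp, "O(1)"), 4)
})

test_that("fingerprint is invariant under rigid motion and atom reordering", {
  s <- random_small_particle(17)
  fp <- build_fingerprint(s, thickness = 3, max_bonds = 8)
  fp_rot <- build_fingerprint(rigid_motion(s, 4), thickness = 3, max_bonds = 8)
  expect_equal(fp_rot$vector[-3], fp$vector[-3])
  expect_equal(fp_rot$vector[3], fp$vector[3], tolerance = 1e-9)

  set.seed(8)
  perm <- sample(n_atoms(s))
  s_perm <- nano_structure(s$elements[perm], s$coords[perm, ])
  fp_perm <- build_fingerprint(s_perm, thickness = 3, max_bonds = 8)
  expect_equal(fp_perm$vector, fp$vector)
})

test_that("section sums equal shell atom and bond counts", {
  for (seed in c(4, 21)) {
    s <- random_small_particle(seed)
    m <- 4L
    fp <- build_fingerprint(s, thickness = 3, max_bonds = m)
    pos <- fp_section_positions(m)
    bg <- fp$bond_graph
    sh <- fp$shell$is_shell
    is_o <- s$elements == "O"
    counted <- sh & bg$degree <= m

    expect_equal(sum(fp$vector[pos$s2_O]), sum(counted & is_o & bg$degree >= 1))
    expect_equal(sum(fp$vector[pos$s2_M]), sum(counted & !is_o & bg$degree >= 1))
    expect_equal(sum(fp$vector[pos$s3_O]), sum(counted & is_o))
    expect_equal(sum(fp$vector[pos$s3_M]), sum(counted & !is_o))

    e <- bg$edges
    both <- counted[e[, 1]] & counted[e[, 2]]
    kind <- is_o[e[, 1]] + is_o[e[, 2]]  # 0 = M-M, 1 = O-M, 2 = O-O
    expect_equal(sum(fp$vector[pos$s4_OO]), sum(both & kind == 2))
    expect_equal(sum(fp$vector[pos$s4_MM]), sum(both & kind == 0))
    expect_equal(sum(fp$vector[pos$s4_OM]), sum(both & kind == 1))

    # per-atom consistency: the section-3 label (x, y) has x + y = degree
    expect_identical(bg$coord_O + bg$coord_M, bg$degree)
  }
})

test_that("fingerprint rejects non-binary oxides", {
  tern <- nano_structure(c("O", "Ti", "Zn"),
                         rbind(c(0, 0, 0), c(1.95, 0, 0), c(-1.9, 0, 0)))
  expect_error(build_fingerprint(tern, 2, 3), "more than one metal")
  no_metal <- nano_structure(c("O", "O"), rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_error(build_fingerprint(no_metal, 2, 3), "no metal")
  no_o <- nano_structure(c("Ti", "Ti"), rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_error(build_fingerprint(no_o, 2, 3), "no oxygen")
})

test_that("diff_fingerprints subtracts counting sections only", {
  s <- random_small_particle(31)
  fp <- build_fingerprint(s, thickness = 3, max_bonds = 4)
  d0 <- diff_fingerprints(fp, fp)
  expect_true(all(d0$delta[-(1:6)] == 0))
  expect_true(all(is.na(d0$delta[1:6])))
  expect_identical(dim(d0$section1), c(2L, 6L))

  fp_other <- build_fingerprint(s, thickness = 3, max_bonds = 5)
  expect_error(diff_fingerprints(fp, fp_other), "max_bonds")
})

test_that("removing a singly coordinated O shows up as an O(1) decrease", {
  s <- particle_with_dangling_o(n_dangle = 3, seed = 2)
  m <- 6L
  th <- compute_size(s) / 2 + 1  # whole particle in shell
  fp_full <- build_fingerprint(s, th, m)
  drop <- n_atoms(s)  # last atom is a dangling O
  expect_identical(s$elements[drop], "O")
  s_less <- nano_structure(s$elements[-drop], s$coords[-drop, ])
  fp_less <- build_fingerprint(s_less, th, m)
  d <- diff_fingerprints(fp_full, fp_less)
  expect_equal(d$delta[index_of("O(1)", m)], 1)
})

test_that("sparse text and CSV serialisation round-trip", {
  s <- random_small_particle(42)
  fp <- build_fingerprint(s, thickness = 3, max_bonds = 5)
  f <- withr::local_tempfile(fileext = ".txt")
  write_fingerprint(fp, f)
  fp2 <- read_fingerprint(f)
  expect_equal(fp2$vector, fp$vector, tolerance = 1e-9)
  expect_identical(fp2$max_bonds, fp$max_bonds)
  expect_identical(fp2$metal, fp$metal)

  fcsv <- withr::local_tempfile(fileext = ".csv")
  write_fingerprint_csv(fp, fcsv)
  df <- read.csv(fcsv)
  expect_identical(nrow(df), as.integer(fingerprint_length(5)))
  expect_equal(df$value, fp$vector)
  expect_identical(df$label[7], "O(1)")
})
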