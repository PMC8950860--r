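test_that("grid layout has 45 nodes with the documented row structure", {
  grid <- grid_layout()
  expect_equal(nrow(grid), 45L)
  counts <- table(grid$row)
  expect_true(all(counts[c("B", "C", "D", "E", "F")] == 7L))
  expect_true(all(counts[c("A", "G")] == 5L))
  # mirror symmetry about column M
  mirrored <- paste0(grid$row, "-", c("J","K","L","M","N","O","P")[8 - grid$col_idx])
  expect_setequal(mirrored, grid$node)
})

test_that("mesh has 64 triangles partitioned 44 RC / 20 AB", {
  mesh <- build_grid_mesh()
  expect_equal(nrow(mesh), 64L)
  expect_equal(sum(mesh$compartment == "RC"), 44L)
  expect_equal(sum(mesh$compartment == "AB"), 20L)
})

test_that("reflecting columns J<->P maps the triangle set onto itself", {
  mesh <- build_grid_mesh()
  cols <- c("J","K","L","M","N","O","P")
  reflect <- function(node) {
    row <- sub("-.*$", "", node)
    ci <- match(sub("^.*-", "", node), cols)
    paste0(row, "-", cols[8 - ci])
  }
  key <- function(a, b, c) {
    apply(cbind(a, b, c), 1, function(x) paste(sort(x), collapse = "|"))
  }
  orig <- sort(key(mesh$n1, mesh$n2, mesh$n3))
  refl <- sort(key(reflect(mesh$n1), reflect(mesh$n2), reflect(mesh$n3)))
  expect_identical(orig, refl)
})

test_that("triangles tile the grid without overlap (areas sum to the strip total)", {
  mesh <- build_grid_mesh()
  pos <- grid_node_template(1)
  tri_area <- function(p1, p2, p3) {
    0.5 * abs((p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2]))
  }
  total <- sum(vapply(seq_len(nrow(mesh)), function(k) {
    tri_area(pos[mesh$n1[k], ], pos[mesh$n2[k], ], pos[mesh$n3[k], ])
  }, numeric(1)))
  # 4 full-width strips (6 column gaps) + 2 boundary strips (4 gaps), cell
  # size row_pitch x col_pitch
  expected <- (4 * 6 + 2 * 4) * 0.07 * 0.06
  expect_equal(total, expected, tolerance = 1e-12)
})

test_that("a single prism contributes projected area times mean height", {
  mesh <- tibble::tibble(triangle = 1L, n1 = "a", n2 = "b", n3 = "c",
                         compartment = "RC")
  # right triangle with legs 0.4 x 0.25 m -> projected area 0.05 m^2
  pos <- rbind(a = c(0, 0, 0.10), b = c(0.4, 0, 0.10), c = c(0, 0.25, 0.10))
  v <- frame_volume(mesh, pos)
  expect_equal(unname(v["CW"]), 5)  # 0.05 m^2 * 0.10 m = 5 L
  expect_equal(unname(v["RC"]), 5)
  expect_equal(unname(v["AB"]), 0)
})

test_that("volumes are invariant to horizontal translation and rotation", {
  mesh <- build_grid_mesh()
  pos <- grid_node_template(1)
  v0 <- frame_volume(mesh, pos)
  shifted <- pos
  shifted[, 1] <- shifted[, 1] + 1.23
  shifted[, 2] <- shifted[, 2] - 0.71
  expect_equal(frame_volume(mesh, shifted), v0, tolerance = 1e-12)
  th <- 0.81
  rot <- pos
  rot[, 1] <- cos(th) * pos[, 1] - sin(th) * pos[, 2]
  rot[, 2] <- sin(th) * pos[, 1] + cos(th) * pos[, 2]
  expect_equal(frame_volume(mesh, rot), v0, tolerance = 1e-10)
})

test_that("raising one node changes V_CW by (delta/3) x sum of incident areas", {
  mesh <- build_grid_mesh()
  pos <- grid_node_template(1)
  node <- "D-M"
  delta <- 0.013
  raised <- pos
  raised[node, 3] <- raised[node, 3] + delta
  dv <- frame_volume(mesh, raised)["CW"] - frame_volume(mesh, pos)["CW"]
  tri_area <- function(k) {
    p1 <- pos[mesh$n1[k], ]; p2 <- pos[mesh$n2[k], ]; p3 <- pos[mesh$n3[k], ]
    0.5 * abs((p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2]))
  }
  incident <- which(mesh$n1 == node | mesh$n2 == node | mesh$n3 == node)
  closed_form <- 1000 * (delta / 3) * sum(vapply(incident, tri_area, numeric(1)))
  expect_equal(unname(dv), closed_form, tolerance = 1e-10)
})

test_that("raising any node never decreases V_CW", {
  mesh <- build_grid_mesh()
  pos <- grid_node_template(1)
  v0 <- frame_volume(mesh, pos)["CW"]
  withr::with_seed(31, {
    for (i in 1:25) {
      node <- sample(rownames(pos), 1)
      raised <- pos
      raised[node, 3] <- raised[node, 3] + runif(1, 0, 0.05)
      expect_gte(frame_volume(mesh, raised)["CW"], v0 - 1e-12)
    }
  })
})

test_that("prism volume equals the sum of three tetrahedra (independent oracle)", {
  tetra_vol <- function(a, b, c, d) {
    abs(det(cbind(b - a, c - a, d - a))) / 6
  }
  withr::with_seed(77, {
    for (i in 1:20) {
      p <- matrix(runif(6, -0.5, 0.5), 3, 2)
      h <- runif(3, 0.05, 0.4)
      top <- cbind(p, h)
      bot <- cbind(p, 0)
      prism <- 0.5 * abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                           (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) * mean(h)
      tets <- tetra_vol(top[1, ], top[2, ], top[3, ], bot[1, ]) +
        tetra_vol(top[2, ], top[3, ], bot[1, ], bot[2, ]) +
        tetra_vol(top[3, ], bot[1, ], bot[2, ], bot[3, ])
      expect_equal(prism, tets, tolerance = 1e-12)
    }
  })
})

test_that("volume series: additivity, constancy, and closed-form oscillation", {
  mesh <- build_grid_mesh()
  pos <- grid_node_template(1)
  n <- 200
  time <- (0:(n - 1)) / 50
  static <- tibble::tibble(time = time)
  osc <- tibble::tibble(time = time)
  a_mm <- 4  # vertical oscillation amplitude, mm
  for (nd in rownames(pos)) {
    static[[paste0(nd, "_X")]] <- rep(1000 * pos[nd, 1], n)
    static[[paste0(nd, "_Y")]] <- rep(1000 * pos[nd, 2], n)
    static[[paste0(nd, "_Z")]] <- rep(1000 * pos[nd, 3], n)
    osc[[paste0(nd, "_X")]] <- rep(1000 * pos[nd, 1], n)
    osc[[paste0(nd, "_Y")]] <- rep(1000 * pos[nd, 2], n)
    osc[[paste0(nd, "_Z")]] <- 1000 * pos[nd, 3] + a_mm * sin(2 * pi * 0.25 * time)
  }
  vs <- compute_volume_series(static, mesh, rate = 50)
  expect_equal(max(vs$V_CW) - min(vs$V_CW), 0)
  expect_equal(vs$V_CW, vs$V_RC + vs$V_AB, tolerance = 1e-14)

  vo <- compute_volume_series(osc, mesh, rate = 50)
  expect_equal(vo$V_CW, vo$V_RC + vo$V_AB, tolerance = 1e-14)
  total_area <- (4 * 6 + 2 * 4) * 0.07 * 0.06          # m^2
  expected_amp <- 1000 * total_area * (a_mm / 1000)     # L
  expect_equal((max(vo$V_CW) - min(vo$V_CW)) / 2, expected_amp, tolerance = 1e-6)
})

test_that("two reference planes give volume series differing by a constant", {
  mesh <- build_grid_mesh()
  pos <- grid_node_template(1)
  withr::with_seed(5, {
    d1 <- vapply(1:10, function(i) {
      p <- pos
      p[, 3] <- p[, 3] + 0.01 * sin(i)
      frame_volume(mesh, p, reference_height = 0)["CW"] -
        frame_volume(mesh, p, reference_height = 0.05)["CW"]
    }, numeric(1))
  })
  expect_lt(diff(range(d1)), 1e-10)
})

test_that("degenerate grids and missing nodes are rejected", {
  grid <- grid_layout()
  expect_error(build_grid_mesh(grid[-1, ]), "45")
  mesh <- build_grid_mesh()
  pos <- grid_node_template(1)
  expect_error(frame_volume(mesh, pos[-match("E-M", rownames(pos)), ]), "E-M")
})
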