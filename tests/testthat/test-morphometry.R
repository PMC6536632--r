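test_that("SWC parsing validates structure and round-trips", {
  p <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment line",
               "1 1 0 0 0 5 -1",
               "2 3 10 0 0 1 1",
               "3 3 20 0 0 1 2"), p)
  tr <- read_swc(p)
  f <- global_morph_features(tr)
  expect_equal(f$n_stems, 1)
  expect_equal(f$n_tips, 1)

  writeLines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 1 2"), p) # own parent
  expect_error(read_swc(p), "cycle", class = "swc_parse_error")
  writeLines(c("1 1 0 0 0 5 -1", "1 3 1 0 0 1 1"), p)
  expect_error(read_swc(p), "duplicate", class = "swc_parse_error")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 1 9"), p)
  expect_error(read_swc(p), "orphan", class = "swc_parse_error")
  writeLines(c("1 1 0 0 0 5 -1", "2 1 1 0 0 5 -1"), p)
  expect_error(read_swc(p), "multiple root", class = "swc_parse_error")

  tr2 <- generate_swc(morph_archetype(spine_density = 0.3), seed = 4)
  write_swc(tr2, p)
  back <- read_swc(p)
  expect_equal(as.data.frame(tibble::as_tibble(tr2)[1:7]),
               as.data.frame(tibble::as_tibble(back)[1:7]),
               tolerance = 1e-8)
})

test_that("global features of simple geometries are exact", {
  f <- global_morph_features(chain_tree(n = 10, seg = 10, radius = 1,
                                        soma_r = 5))
  expect_equal(f$n_bifurcations, 0)
  expect_equal(f$n_tips, 1)
  expect_equal(f$total_length_um, 100)
  expect_equal(f$avg_contraction, 1.0)
  expect_equal(f$max_path_um, 100)
  expect_equal(f$max_euclidean_um, 100)
  expect_equal(f$soma_surface_um2, 4 * pi * 25)
  expect_equal(f$avg_diameter_um, 2)

  y <- global_morph_features(y_tree())
  expect_equal(y$n_stems, 1)
  expect_equal(y$n_bifurcations, 1)
  expect_equal(y$n_branches, 3)
  expect_equal(y$n_tips, 2)
  expect_equal(y$max_branch_order, 2) # soma = 0, stem 1, daughters 2
  expect_equal(y$avg_local_amp_angle_deg, 90, tolerance = 1e-6)
})

test_that("Sholl counts match straight-line expectations", {
  straight <- chain_tree(n = 10, seg = 10) # 100 um along +x
  prof <- sholl_profile(straight, radii = c(30, 50, 99, 120))
  expect_equal(prof$intersections, c(1, 1, 1, 0))

  y <- y_tree(stem = 20, arm = 30)
  expect_equal(sholl_profile(y, radii = 30)$intersections, 2)
})

test_that("surface-area profile conserves total lateral area", {
  cyl <- chain_tree(n = 10, seg = 10, radius = 1, soma_r = 1)
  prof <- surface_area_profile(cyl, bin_width = 10)
  expect_equal(nrow(prof), 10)
  expect_true(all(abs(prof$area_um2 - 2 * pi * 10) < 1e-9))
  expect_true(all(prof$bin_start_um < 100)) # nothing beyond max path

  tr <- generate_swc(morph_archetype(n_stems = 4, branch_prob_per_um = 0.015,
                                     spine_density = 0.4), seed = 6)
  prof2 <- surface_area_profile(tr)
  expect_equal(sum(prof2$area_um2), oracle_lateral_area(tr),
               tolerance = 1e-9)
})

test_that("spine density divides spine count by dendritic length", {
  tr <- chain_tree(n = 10, seg = 10)
  nd <- tibble::as_tibble(tr)[1:7]
  spines <- tibble::tibble(
    id = 100 + 1:50, type = 8, x = rep(nd$x[2:11], 5), y = 1, z = 0,
    radius = 0.3, parent = rep(nd$id[2:11], 5)
  )
  spiny <- neuron_tree(dplyr::bind_rows(nd, spines))
  expect_equal(spine_density(spiny), 0.5)
  expect_equal(spine_density(tr), 0)

  dense <- generate_swc(striatal_archetypes()$MSN$morph, seed = 8)
  L <- sum(dense$nodes$comp_length[dense$nodes$type == 3])
  expect_lt(abs(spine_density(dense) - 0.57), 3 * sqrt(0.57 * L) / L)
})

test_that("all count and geometry features match the recursive oracle", {
  for (s in 1:30) {
    tr <- generate_swc(random_morph_spec(s), seed = s)
    f <- global_morph_features(tr)
    o <- oracle_morph(tr)
    expect_identical(as.integer(f$n_nodes), as.integer(o$n_nodes))
    expect_identical(as.integer(f$n_stems), as.integer(o$n_stems))
    expect_identical(as.integer(f$n_bifurcations), as.integer(o$n_bifurcations))
    expect_identical(as.integer(f$n_branches), as.integer(o$n_branches))
    expect_identical(as.integer(f$n_tips), as.integer(o$n_tips))
    expect_identical(as.integer(f$max_branch_order), as.integer(o$max_order))
    expect_equal(f$total_length_um, o$total_length, tolerance = 1e-6)
    expect_equal(f$total_volume_um3, o$total_volume, tolerance = 1e-6)
    expect_equal(f$max_path_um, o$max_path, tolerance = 1e-6)
    expect_equal(f$max_euclidean_um, o$max_euclidean, tolerance = 1e-6)
    expect_equal(f$avg_contraction, o$avg_contraction, tolerance = 1e-6)
    expect_equal(f$avg_fragmentation, o$avg_fragmentation, tolerance = 1e-6)
    for (r in c(20, 40, 60)) {
      expect_identical(sholl_profile(tr, r)$intersections,
                       as.numeric(oracle_sholl(tr, r)))
    }
  }
})

test_that("features are invariant to rigid motion and scale as dimensioned", {
  tr <- generate_swc(random_morph_spec(99), seed = 99)
  nd <- tibble::as_tibble(tr)[1:7]

  # rigid rotation about z plus translation
  th <- 0.7
  rot <- nd
  rot$x <- cos(th) * nd$x - sin(th) * nd$y + 40
  rot$y <- sin(th) * nd$x + cos(th) * nd$y - 15
  f0 <- global_morph_features(tr)
  f1 <- global_morph_features(neuron_tree(rot))
  invariant <- setdiff(morph_feature_names(),
                       c("height_um", "width_um", "depth_um"))
  for (f in invariant) {
    expect_equal(f1[[f]], f0[[f]], tolerance = 1e-8, label = f)
  }

  # uniform scaling: length ~ s, volume ~ s^3, angles unchanged
  sc <- nd
  sc[c("x", "y", "z", "radius")] <- sc[c("x", "y", "z", "radius")] * 2
  f2 <- global_morph_features(neuron_tree(sc))
  expect_equal(f2$total_length_um, 2 * f0$total_length_um, tolerance = 1e-9)
  expect_equal(f2$total_volume_um3, 8 * f0$total_volume_um3, tolerance = 1e-9)
  expect_equal(f2$avg_local_amp_angle_deg, f0$avg_local_amp_angle_deg,
               tolerance = 1e-9)
  expect_equal(f2$avg_contraction, f0$avg_contraction, tolerance = 1e-9)
})
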