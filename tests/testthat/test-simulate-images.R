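test_that("image simulation is deterministic under a fixed seed", {
  cfg <- img_sim_config(seed = 13, image_shape = c(256, 256), n_nuclei = 4,
                        cluster_spec = list(n_clusters = 1, cluster_size = 2))
  expect_identical(simulate_images(cfg, paired = TRUE),
                   simulate_images(cfg, paired = TRUE))
})

test_that("noise-free single nucleus matches its truth mask exactly", {
  cfg <- img_sim_config(seed = 1, image_shape = c(128, 128), n_nuclei = 1,
                        cluster_spec = list(n_clusters = 0, cluster_size = 0),
                        noise_sd = 0)
  b <- simulate_images(cfg)$baseline[[1]]
  truth <- b$truth$nuclei[[1]]
  expect_equal(sum(b$dna > 0), truth$area)
  expect_setequal(which(b$dna > 0), truth$pixels)
  # density classes partition the mask at the configured fractions
  cm <- b$truth$class_map
  expect_equal(sum(cm > 0), truth$area)
  expect_equal(sum(cm == 3), round(truth$area * 0.2))
  expect_equal(sum(cm == 2), round(truth$area * 0.3))
  expect_true(all(cm[b$dna == 0] == 0))   # no class outside nuclei
})

test_that("cluster masks are disjoint, connected, one foreground component", {
  cfg <- img_sim_config(seed = 4, image_shape = c(192, 192), n_nuclei = 2,
                        cluster_spec = list(n_clusters = 1, cluster_size = 2),
                        noise_sd = 0)
  b <- simulate_images(cfg)$baseline[[1]]
  n1 <- b$truth$nuclei[[1]]; n2 <- b$truth$nuclei[[2]]
  expect_length(intersect(n1$pixels, n2$pixels), 0)
  fg <- matrix(0L, 192, 192)
  fg[c(n1$pixels, n2$pixels)] <- 1L
  expect_equal(max(EBImage::bwlabel(fg)), 1)   # union is connected
  for (nn in list(n1, n2)) {
    m <- matrix(0L, 192, 192); m[nn$pixels] <- 1L
    expect_equal(max(EBImage::bwlabel(m)), 1)  # each mask is connected
  }
})

test_that("truth HP1 positivity tracks the configured occupancies", {
  sim <- simulate_images(img_sim_config(seed = 7))
  t <- sim$baseline[[1]]$truth
  occ <- vapply(1:3, function(k) mean(t$hp1_pos[t$class_map == k]),
                numeric(1))
  expect_true(all(abs(occ - c(0.2, 0.5, 0.8)) <= 0.03))
  expect_true(all(diff(occ) > 0))
  # background carries no HP1 truth
  expect_false(any(t$hp1_pos[t$class_map == 0]))
})

test_that("the dispersed pair doubles every nucleus area exactly", {
  cfg <- img_sim_config(seed = 5, noise_sd = 0)
  sim <- simulate_images(cfg, paired = TRUE)
  a0 <- vapply(sim$baseline[[1]]$truth$nuclei, `[[`, numeric(1), "area")
  a1 <- vapply(sim$dispersed[[1]]$truth$nuclei, `[[`, numeric(1), "area")
  expect_identical(a1, 2 * a0)
})

test_that("invalid image configurations are rejected", {
  expect_error(img_sim_config(class_intensity_means = c(100, 90, 200)),
               "increasing")
  expect_error(img_sim_config(hp1_occupancy = c(0.5, 0.4, 0.8)),
               "non-decreasing")
  expect_error(img_sim_config(density_fractions = c(loose = 0.5,
                                                    middle = 0.5,
                                                    dense = 0.5)),
               "sum to 1")
  expect_error(img_sim_config(n_nuclei = 2,
                              cluster_spec = list(n_clusters = 2,
                                                  cluster_size = 2)),
               "more nuclei")
  expect_error(simulate_images(img_sim_config(image_shape = c(64, 64))),
               "too small")
})

test_that("TIFF round trip preserves both channels", {
  sim <- simulate_images(img_sim_config(seed = 3, image_shape = c(160, 160),
                                        n_nuclei = 2,
                                        cluster_spec = list(n_clusters = 0,
                                                            cluster_size = 0)))
  img <- sim$baseline[[1]]
  p <- tempfile(fileext = ".tif")
  write_image_tiff(img, p)
  back <- read_image_tiff(p)
  expect_equal(back$dna, matrix(as.numeric(img$dna), nrow(img$dna)))
  expect_equal(back$hp1, matrix(as.numeric(img$hp1), nrow(img$hp1)))
})
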