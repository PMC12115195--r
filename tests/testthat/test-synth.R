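test_that("zero-lesion scenes carry empty annotation lists", {
  cfg <- scene_config("sunny", image_size = 64, seed = 1)
  s <- generate_scene(cfg, n_lesions = 0)
  expect_equal(nrow(s$annotations), 0)
  expect_equal(dim(s$image), c(64L, 64L, 3L))
})

test_that("every emitted box is inside the unit square with positive area", {
  for (i in 1:6) {
    cfg <- scene_config(c("sunny", "cloudy", "dense")[1 + i %% 3],
                        image_size = 96, seed = i)
    s <- generate_scene(cfg)
    a <- s$annotations
    expect_true(all(a$w > 0 & a$h > 0))
    expect_true(all(a$cx - a$w / 2 >= -1e-9 & a$cx + a$w / 2 <= 1 + 1e-9))
    expect_true(all(a$cy - a$h / 2 >= -1e-9 & a$cy + a$h / 2 <= 1 + 1e-9))
  }
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- scene_config("dense", image_size = 80, seed = 123)
  s1 <- generate_scene(cfg); s2 <- generate_scene(cfg)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$annotations, s2$annotations)
  m1 <- generate_dataset(12, c(4, 3, 3), out_root = NULL, seed = 5,
                         image_size = 64)
  m2 <- generate_dataset(12, c(4, 3, 3), out_root = NULL, seed = 5,
                         image_size = 64)
  digest_manifest <- function(m)
    vapply(m$records, function(r) paste(unlist(r$annotations), collapse = ","),
           character(1))
  expect_identical(digest_manifest(m1), digest_manifest(m2))
})

test_that("dominant-class counts follow the configured ratio", {
  expect_equal(largest_remainder(4000, c(4, 3, 3)), c(1600L, 1200L, 1200L))
  expect_equal(largest_remainder(10, c(4, 3, 3)), c(4L, 3L, 3L))
  m <- generate_dataset(20, c(4, 3, 3), out_root = NULL, seed = 2,
                        image_size = 64)
  doms <- table(vapply(m$records, `[[`, integer(1), "dominant"))
  expect_equal(unname(c(doms)), c(8, 6, 6))
  expect_error(generate_dataset(2, c(4, 3, 3)), "below class count")
})

test_that("lesion classes are recoverable from geometry at >= 95% accuracy", {
  ok <- 0L; tot <- 0L
  i <- 0L
  while (tot < 500L) {
    i <- i + 1L
    cfg <- scene_config(c("sunny", "cloudy", "dense")[1 + i %% 3],
                        image_size = 128, seed = 1000 + i)
    s <- generate_scene(cfg)
    for (b in seq_len(nrow(s$annotations))) {
      tot <- tot + 1L
      ok <- ok + (classify_lesion(s$image, s$annotations[b, ]) ==
                    s$annotations$class_id[b])
    }
  }
  expect_gte(ok / tot, 0.95)
})

test_that("dense planting overlaps boxes more often than sunny scenes", {
  overlap_count <- function(scenario) {
    total <- 0
    for (i in 1:25) {
      s <- generate_scene(scene_config(scenario, image_size = 96, seed = i,
                                       lesions_per_image = c(5, 5)))
      g <- anns_to_gt(s$annotations)
      if (nrow(g) > 1) {
        for (a in 1:(nrow(g) - 1)) for (b in (a + 1):nrow(g)) {
          if (iou(as.numeric(g[a, 2:5]), as.numeric(g[b, 2:5])) > 0)
            total <- total + 1
        }
      }
    }
    total
  }
  expect_gt(overlap_count("dense"), overlap_count("sunny"))
})
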