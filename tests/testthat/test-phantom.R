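test_that("phantom generation is deterministic and validates its spec", {
  sp <- phantom_spec(seed = 1L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$pixels, b$pixels)
  expect_true(all(a$pixels >= 0 & a$pixels <= 255))
  expect_error(phantom_spec(image_side = 241L), "even")
  expect_error(phantom_spec(lesion_longest_axis = 1), "\\[2, 105\\]")
  expect_error(phantom_spec(lesion_longest_axis = 106), "\\[2, 105\\]")
  expect_error(phantom_spec(lesion_contrast = 0.9), "contrast")
})

test_that("lesion-free phantoms are negative with bounded tissue intensities", {
  sp <- phantom_spec(lesion_count = 0L, seed = 7L)
  ph <- generate_phantom(sp)
  expect_identical(ph$label, 0L)
  brain <- ph$metadata$brain_mask
  tissue <- ph$pixels[brain]
  expect_lt(max(tissue), mean(tissue) + 6 * sp$tissue_noise_sd)
})

test_that("label is positive exactly when lesions are present", {
  expect_identical(generate_phantom(phantom_spec(lesion_count = 2L,
                                                seed = 3L))$label, 1L)
  expect_identical(generate_phantom(phantom_spec(lesion_count = 0L,
                                                seed = 3L))$label, 0L)
})

test_that("measured lesion longest axis tracks the requested axis within a pixel", {
  for (axis in c(2, 10, 50, 105)) {
    ph <- generate_phantom(phantom_spec(lesion_longest_axis = axis,
                                        seed = 11L + axis))
    measured <- mask_longest_axis(ph$metadata$lesion_mask)
    expect_lte(abs(measured - axis), 1,
               label = sprintf("axis %g measured %.2f", axis, measured))
  }
})

test_that("the study-composition preset reproduces the published counts", {
  man <- generate_dataset("study", seed = 5L)
  expect_equal(sum(man$split == "train"), 382L)
  expect_equal(sum(man$split == "test"), 190L)
  tab <- table(man$class[man$split == "train"])
  expect_equal(as.integer(tab[c("non_pathological", "other_disease",
                                "glioma", "meningioma", "pituitary")]),
               c(168L, 151L, 34L, 20L, 9L))
  tab2 <- table(man$class[man$split == "test"])
  expect_equal(as.integer(tab2[c("non_pathological", "other_disease",
                                 "glioma", "meningioma", "pituitary")]),
               c(10L, 90L, 30L, 30L, 30L))
  # split hygiene: no slice id in both splits
  expect_length(intersect(man$id[man$split == "train"],
                          man$id[man$split == "test"]), 0L)
})

test_that("positive-class choice controls the labels, not the rendering", {
  g <- generate_dataset("study", seed = 5L, positive_class = "glioma")
  t <- generate_dataset("study", seed = 5L, positive_class = "any-tumor")
  expect_equal(sum(g$label[g$split == "test"]), 30L)
  expect_equal(sum(t$label[t$split == "test"]), 90L)
  expect_identical(g$seed, t$seed)  # identical phantoms either way
})

test_that("an all-zero composition yields an empty manifest", {
  comp <- data.frame(class = "glioma", train = 0L, test = 0L)
  man <- generate_dataset(comp, seed = 1L)
  expect_equal(nrow(man), 0L)
  expect_equal(nrow(augment_x2(man)), 0L)
})

test_that("augmentation doubles the manifest, preserves labels, and is seeded", {
  comp <- data.frame(class = c("glioma", "non_pathological"),
                     train = c(4L, 4L), test = c(2L, 2L))
  man <- generate_dataset(comp, seed = 9L)
  aug1 <- augment_x2(man, seed = 2L)
  aug2 <- augment_x2(man, seed = 2L)
  expect_equal(nrow(aug1), 2L * nrow(man))
  expect_identical(as.data.frame(aug1), as.data.frame(aug2))
  copies <- aug1[aug1$augmented, ]
  expect_equal(copies$label,
               man$label[match(copies$source_id, man$id)])
  # a full study-composition manifest doubles to the published 764
  expect_equal(nrow(augment_x2(generate_dataset("study", seed = 1L)[
    generate_dataset("study", seed = 1L)$split == "train", , drop = FALSE
  ])), 764L)
})

test_that("augmented slices materialize deterministically and differ from originals", {
  comp <- data.frame(class = "glioma", train = 2L, test = 0L)
  man <- augment_x2(generate_dataset(comp, seed = 13L), seed = 3L)
  orig <- manifest_slice(man, 1L)
  aug_a <- manifest_slice(man, 3L)
  aug_b <- manifest_slice(man, 3L)
  expect_identical(aug_a$pixels, aug_b$pixels)
  expect_false(identical(orig$pixels, aug_a$pixels))
  expect_identical(aug_a$label, orig$label)
  expect_equal(dim(aug_a$pixels), dim(orig$pixels))
})
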