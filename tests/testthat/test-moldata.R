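test_that("structure invariants are enforced", {
  expect_error(structure_new("s", "g", c(0L, 1L), matrix(0:5, 2, 3)),
               "atomic numbers")
  expect_error(structure_new("s", "g", c(1L, 1L),
                             matrix(c(0, 0, 0, 0, NA, 0), 2, 3,
                                    byrow = TRUE)),
               "non-finite")
  expect_error(structure_new("s", "g", c(1L, 1L),
                             matrix(0, 2, 3)), "coincident")
  expect_error(structure_new("s", "g", c(1L, 1L, 1L), matrix(1:6, 2, 3)),
               "n x 3")
})

test_that("extended-XYZ write/read round trip preserves data", {
  structs <- lapply(1:3, function(i) {
    s <- random_structure(3 + i, seed = i, id = paste0("s", i),
                          gid = paste0("g", (i + 1) %/% 2))
    s$properties <- list(energy = i * 1.5 - 2, gap = -0.1 * i)
    s
  })
  path <- withr::local_tempfile(fileext = ".extxyz")
  write_structures(structs, path)
  back <- read_structures(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$atomic_numbers, structs[[i]]$atomic_numbers)
    expect_identical(back[[i]]$structure_id, structs[[i]]$structure_id)
    expect_identical(back[[i]]$group_id, structs[[i]]$group_id)
    expect_lt(max(abs(back[[i]]$positions - structs[[i]]$positions)), 1e-6)
    expect_equal(back[[i]]$properties$energy, structs[[i]]$properties$energy)
    expect_equal(back[[i]]$properties$gap, structs[[i]]$properties$gap)
  }
})

test_that("element symbols map to atomic numbers and back", {
  expect_identical(symbol_to_z(c("H", "C", "Cl")), c(1L, 6L, 17L))
  expect_identical(z_to_symbol(c(8L, 35L)), c("O", "Br"))
  expect_error(symbol_to_z("Xx"), "unknown element")
})

test_that("malformed frames are reported with their index", {
  path <- withr::local_tempfile(fileext = ".extxyz")
  good <- "2\ngroup_id=g1\nH 0 0 0\nH 1 0 0\n"
  bad <- "2\ngroup_id=g2\nH 0 0 0\nH NaN 0 0\n"
  writeLines(paste0(good, good, bad), path)
  expect_error(read_structures(path), "frame 3")
  path2 <- withr::local_tempfile(fileext = ".extxyz")
  writeLines(paste0(good, "2\nnote=missing_ids\nH 0 0 0\nH 1 0 0\n"), path2)
  expect_error(read_structures(path2), "group_id")
})

test_that("plain XYZ with a sidecar table attaches metadata", {
  xyz <- withr::local_tempfile(fileext = ".xyz")
  writeLines("2\nconfA\nH 0 0 0\nO 1 0 0\n2\nconfB\nH 0 0 0\nO 1.1 0 0\n",
             xyz)
  side <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("structure_id,group_id,energy",
               "confA,m1,-3.5", "confB,m1,-3.1"), side)
  got <- read_structures(xyz, format = "xyz", sidecar = side)
  expect_identical(got[[2]]$group_id, "m1")
  expect_equal(got[[1]]$properties$energy, -3.5)
  expect_identical(got[[2]]$atomic_numbers, c(1L, 8L))
})

test_that("grouping partitions structures and conserves counts", {
  structs <- c(
    lapply(1:4, function(i) random_structure(3, seed = i,
                                             id = paste0("a", i),
                                             gid = "g1")),
    lapply(1:2, function(i) random_structure(3, seed = 10 + i,
                                             id = paste0("b", i),
                                             gid = "g2"))
  )
  groups <- group_structures(structs)
  expect_length(groups, 2)
  expect_identical(vapply(groups, length, integer(1)), c(4L, 2L))
  expect_identical(group_structures(list()), list())
  # a large single-molecule ensemble: 1 base + 100 perturbed copies
  big <- lapply(1:101, function(i) random_structure(3, seed = i,
                                                    id = paste0("c", i),
                                                    gid = "m"))
  expect_identical(vapply(group_structures(big), length, integer(1)), 101L)
})

test_that("molecule-level split is seeded, disjoint, and exhaustive", {
  groups <- lapply(1:100, function(i) {
    conformer_group(paste0("g", i),
                    list(random_structure(3, seed = i, gid = paste0("g", i))))
  })
  sp <- split_by_molecule(groups, 0.05, seed = 7)
  expect_length(sp$test_groups, 5)
  expect_length(sp$train_groups, 95)
  expect_length(intersect(sp$train_groups, sp$test_groups), 0)
  expect_setequal(c(sp$train_groups, sp$test_groups),
                  paste0("g", 1:100))
  expect_identical(sp, split_by_molecule(groups, 0.05, seed = 7))
  expect_false(identical(sp$test_groups,
                         split_by_molecule(groups, 0.05, seed = 8)$test_groups))
  # invariants hold across random fractions/seeds
  for (k in 1:10) {
    spk <- split_by_molecule(groups, runif(1, 0.05, 0.9), seed = k)
    expect_length(intersect(spk$train_groups, spk$test_groups), 0)
    expect_length(c(spk$train_groups, spk$test_groups), 100)
  }
  expect_error(split_by_molecule(groups[1], 0.5), "at least 2")
  expect_error(split_by_molecule(groups, 1.5), "in \\(0, 1\\)")
})

test_that("group filtering drops small groups and caps large ones", {
  sizes <- c(3L, 5L, 6L, 8L, 20L)
  groups <- lapply(seq_along(sizes), function(i) {
    conformer_group(paste0("g", i), lapply(seq_len(sizes[i]), function(k) {
      random_structure(3, seed = i * 100 + k, id = paste0("g", i, "_", k),
                       gid = paste0("g", i))
    }))
  })
  out <- filter_and_cap_groups(groups, min_exclusive = 5L, cap = 11L,
                               seed = 3)
  expect_identical(vapply(out, function(g) g$group_id, character(1)),
                   c("g3", "g4", "g5"))
  expect_identical(vapply(out, length, integer(1)), c(6L, 8L, 11L))
  # never increases a size, never drops a group above the threshold
  out2 <- filter_and_cap_groups(groups, min_exclusive = 2L, cap = 5L)
  expect_identical(vapply(out2, length, integer(1)), c(3L, 5L, 5L, 5L, 5L))
  # capped members are a subset of the original ensemble
  ids20 <- vapply(groups[[5]]$structures, function(s) s$structure_id,
                  character(1))
  kept <- vapply(out[[3]]$structures, function(s) s$structure_id,
                 character(1))
  expect_true(all(kept %in% ids20))
})

test_that("pair labels follow the property comparison rule", {
  g <- small_group(4, seed = 2)
  pairs <- make_pairs(g, "energy", seed = 5)
  expect_length(pairs, choose(4, 2))
  for (pr in pairs) {
    ta <- pr$a$properties$energy
    tb <- pr$b$properties$energy
    expect_equal(pr$target_diff, ta - tb)
    expect_equal(sum(pr$label), 1)
    if (ta > tb) expect_identical(pr$label, c(1, 0))
    if (ta < tb) expect_identical(pr$label, c(0, 1))
    # label/target consistency both ways
    if (identical(pr$label, c(1, 0))) expect_gt(pr$target_diff, 0)
    if (identical(pr$label, c(0, 1))) expect_lt(pr$target_diff, 0)
  }
  # explicit value check
  s1 <- g$structures[[1]]; s2 <- g$structures[[2]]
  s1$properties$energy <- 3.0; s2$properties$energy <- 1.0
  gg <- conformer_group(g$group_id, list(s1, s2))
  pr <- make_pairs(gg, "energy", seed = 1)[[1]]
  expect_identical(abs(pr$target_diff), 2.0)
  expect_identical(sort(pr$label, decreasing = TRUE), c(1, 0))
  # ties
  s2$properties$energy <- 3.0
  gt <- conformer_group(g$group_id, list(s1, s2))
  pt <- make_pairs(gt, "energy", seed = 1)[[1]]
  expect_identical(pt$label, c(0.5, 0.5))
  expect_identical(pt$target_diff, 0)
})

test_that("pair budget and missing properties are handled", {
  g <- small_group(6, seed = 3)
  expect_length(make_pairs(g, "energy", budget = 4, seed = 1), 4)
  expect_length(make_pairs(g, "energy", budget = 100, seed = 1),
                choose(6, 2))
  g$structures[[2]]$properties$energy <- NULL
  expect_error(make_pairs(g, "energy"), "g1_s2")
})
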