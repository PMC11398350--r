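test_that("state-space size is 3^B - 2^B, checked against brute force", {
  for (B in 1:5) {
    sp <- enumerate_states(B)
    all_codes <- as.matrix(expand.grid(rep(list(0:2), B)))
    expect_equal(sp$n_states, sum(rowSums(all_codes == 2) >= 1))
    expect_equal(sp$n_states, 3^B - 2^B)
    expect_false(anyDuplicated(sp$digits) > 0)
    expect_true(all(rowSums(sp$codes == 2) >= 1))
  }
  expect_equal(enumerate_states(1)$codes, matrix(2L, 1, 1))
})

test_that("canonical order is lexicographic and indices are stable", {
  sp <- enumerate_states(2, c("H", "C"))
  expect_equal(sp$digits, c("02", "12", "20", "21", "22"))
  expect_equal(sp$state_labels, c("C", "hC", "H", "Hc", "HC"))
  expect_equal(state_index(sp, "Hc"), 4L)
  expect_equal(state_index(sp, "21"), 4L)
  expect_equal(state_index(sp, c(2L, 1L)), 4L)
})

test_that("labels follow the case convention and parse back", {
  labs <- c("T", "W", "C")
  expect_equal(state_label(c(2, 1, 0), labs), "Tw")
  expect_equal(state_label(c(2, 1), c("H", "C")), "Hc")
  expect_equal(state_label(c(2, 2), c("H", "C")), "HC")
  for (B in 1:4) {
    sp <- enumerate_states(B)
    for (i in seq_len(sp$n_states))
      expect_equal(parse_state_label(sp$state_labels[i], sp$labels),
                   unname(sp$codes[i, ]))
  }
  expect_error(enumerate_states(2, c("Hot", "hot")), "distinct first letters")
  expect_error(enumerate_states(0), "n_biomes")
})

test_that("worst-case coding admits 2^k states and the printed 4-state set", {
  obs <- tip_observation("v1", c("2", "?", "?"))
  m <- compatible_states(obs, NULL, space3)
  expect_equal(sort(space3$digits[m$mask == 1]),
               c("200", "201", "210", "211"))
  set.seed(42)
  for (rep in 1:20) {
    codes <- space3$codes[sample.int(space3$n_states, 1), ]
    cells <- ifelse(codes == 2, "2", "?")
    m <- compatible_states(tip_observation("x", cells), NULL, space3)
    expect_equal(sum(m$mask), 2^sum(codes != 2))
    # every admitted state reproduces the observed established pattern
    adm <- space3$codes[m$mask == 1, , drop = FALSE]
    expect_true(all(t(adm == 2) == (codes == 2)))
  }
})

test_that("fully specified observations give singleton masks", {
  m <- compatible_states(tip_observation("x", c("2", "1", "0")), NULL, space3)
  expect_equal(space3$digits[m$mask == 1], "210")
})

test_that("include forces enabled, exclude forces non-affinity", {
  obs <- tip_observation("v1", c("2", "?", "?"))
  inc <- constraint_set(includes = data.frame(species = "v1", biome = "C"))
  m <- compatible_states(obs, inc, space3)
  expect_equal(sort(space3$digits[m$mask == 1]), c("201", "211"))
  exc <- constraint_set(excludes = data.frame(species = "v1", biome = "W"))
  m2 <- compatible_states(obs, exc, space3)
  expect_equal(sort(space3$digits[m2$mask == 1]), c("200", "201"))
  # excluding an established biome is contradictory
  expect_error(
    compatible_states(obs, constraint_set(
      excludes = data.frame(species = "v1", biome = "T")), space3),
    "established")
})

test_that("adjacency rule drops gradient-bracketed gaps at tips", {
  # established tropical and cold temperate: warm temperate must be >= 1
  obs <- tip_observation("v2", c("2", "?", "2"))
  m0 <- compatible_states(obs, NULL, space3)
  expect_equal(sort(space3$digits[m0$mask == 1]), c("202", "212"))
  m1 <- compatible_states(obs, constraint_set(adjacency = c("T", "W", "C")),
                          space3)
  expect_equal(space3$digits[m1$mask == 1], "212")
  # the extended mode also fires on enabled flanks
  obs2 <- tip_observation("v3", c("2", "?", "1"))
  m2 <- compatible_states(obs2, constraint_set(adjacency = c("T", "W", "C")),
                          space3)
  expect_true("201" %in% space3$digits[m2$mask == 1])
  m3 <- compatible_states(obs2, constraint_set(adjacency = c("T", "W", "C"),
                                               adjacency_mode = "affinity"),
                          space3)
  expect_false("201" %in% space3$digits[m3$mask == 1])
})

test_that("constraints never enlarge a mask (anti-monotonicity)", {
  set.seed(7)
  for (rep in 1:10) {
    codes <- space3$codes[sample.int(space3$n_states, 1), ]
    obs <- tip_observation("x", ifelse(codes == 2, "2", "?"))
    base <- compatible_states(obs, NULL, space3)$mask
    unest <- space3$labels[codes != 2]
    if (!length(unest)) next
    b <- sample(unest, 1)
    for (cs in list(
      constraint_set(includes = data.frame(species = "x", biome = b)),
      constraint_set(excludes = data.frame(species = "x", biome = b)),
      constraint_set(adjacency = c("T", "W", "C")))) {
      refined <- compatible_states(obs, cs, space3)$mask
      expect_true(all(refined <= base))
    }
  }
})
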