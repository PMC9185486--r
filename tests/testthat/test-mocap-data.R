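test_that("sequence construction validates shapes and absorbs non-finite samples", {
  pos <- array(rnorm(2 * 3 * 3), c(3, 2, 3))
  s <- mocap_sequence(pos, c("A", "B"), 100)
  expect_s3_class(s, "mocap_sequence")
  expect_equal(n_frames(s), 3)
  expect_equal(n_markers(s), 2)
  expect_error(mocap_sequence(pos, c("A"), 100), "labels")
  expect_error(mocap_sequence(pos, c("A", "A"), 100), "unique")
  expect_error(mocap_sequence(pos, c("A", "B"), -1), "fps")
  pos[2, 1, 2] <- NaN
  s2 <- mocap_sequence(pos, c("A", "B"), 100)
  expect_true(s2$gap_mask[2, 1])
  expect_true(all(is.na(s2$positions[2, 1, ])))
})

test_that("CSV fixture with 2 markers and 3 frames parses to shape (3, 2, 3)", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("# fps=120",
               "A_x,A_y,A_z,B_x,B_y,B_z",
               "1,2,3,4,5,6",
               "1.5,2.5,3.5,4.5,5.5,6.5",
               "2,3,4,5,6,7"), f)
  s <- load_sequence(f)
  expect_equal(s$fps, 120)
  expect_equal(dim(s$positions), c(3, 2, 3))
  expect_equal(s$labels, c("A", "B"))
  expect_equal(s$positions[1, "B", ], c(x = 4, y = 5, z = 6))
})

test_that("save/load round-trips both dialects, with gaps as missing tokens", {
  set.seed(7)
  pos <- array(rnorm(5 * 3 * 3, 0, 100), c(5, 3, 3))
  pos[3, 2, ] <- NA
  s <- mocap_sequence(pos, c("HIP", "KNEE", "ANK"), 100)
  for (fmt in c("csv", "trc")) {
    f <- tempfile(fileext = paste0(".", fmt))
    save_sequence(s, f)
    # gaps serialised as the empty token, never 0
    body <- readLines(f)
    expect_false(any(grepl(",0,0,0|\t0\t0\t0", body)))
    s2 <- load_sequence(f)
    expect_equal(s2$fps, s$fps)
    expect_equal(s2$labels, s$labels)
    expect_equal(s2$positions, s$positions, tolerance = 1e-8)
    expect_equal(s2$gap_mask, s$gap_mask, ignore_attr = TRUE)
  }
})

test_that("TRC metadata carries the 100 Hz sampling rate through a round-trip", {
  g <- make_group_seq(n = 10)
  f <- tempfile(fileext = ".trc")
  save_sequence(g$seq, f)
  expect_equal(load_sequence(f, "trc")$fps, 100)
})

test_that("an empty-marker sequence saves as a header-only file", {
  s <- mocap_sequence(array(numeric(0), c(0, 2, 3)), c("A", "B"), 100)
  f <- tempfile(fileext = ".csv")
  save_sequence(s, f)
  expect_length(readLines(f), 2)
  expect_equal(n_frames(load_sequence(f)), 0)
})

test_that("c3d is refused with an informative error", {
  f <- tempfile(fileext = ".c3d")
  file.create(f)
  expect_error(load_sequence(f), "C3D")
})

test_that("hierarchy validation accepts chains and rejects violations", {
  h <- body_hierarchy(
    groups = list(head = c("H1", "H2"), neck = c("N1", "N2"),
                  torso = c("T1", "T2")),
    parents = list(head = "neck", neck = "torso"))
  expect_s3_class(h, "body_hierarchy")
  expect_true(is.na(h$parent[["torso"]]))
  expect_error(body_hierarchy(
    groups = list(a = c("M1", "M2"), b = c("M2", "M3")),
    parents = list(b = "a")), "more than one group")
  expect_error(body_hierarchy(
    groups = list(a = "M1", b = "M2"),
    parents = list(a = "b", b = "a")), "tree|cycle")
})

test_that("random non-tree parent maps are all rejected", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(3:6, 1)
    gn <- paste0("g", seq_len(k))
    groups <- setNames(lapply(gn, function(g) paste0(g, "_m")), gn)
    # parent map with at least one cycle: a random functional graph where
    # every group has a parent must contain a cycle
    parents <- setNames(as.list(sample(gn, k, replace = TRUE)), gn)
    for (g in gn) while (identical(parents[[g]], g))
      parents[[g]] <- sample(gn, 1)
    expect_error(body_hierarchy(groups, parents))
  }
})

test_that("hierarchy configs load from YAML and JSON, including the bundled mesh", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("groups:",
               "  torso: [T1, T2]",
               "  head: [H1, H2]",
               "parents:",
               "  head: torso"), f)
  h <- load_hierarchy(f)
  expect_equal(h$parent[["head"]], "torso")
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(groups = list(torso = c("T1", "T2"),
                                          head = c("H1", "H2")),
                            parents = list(head = "torso")),
                       fj, auto_unbox = TRUE)
  expect_equal(load_hierarchy(fj)$parent[["head"]], "torso")
  bundled <- system.file("extdata", "fbm16_synthetic.yaml",
                         package = "mocapclean")
  hb <- load_hierarchy(bundled)
  expect_length(unlist(hb$groups), 16)
  expect_equal(sum(is.na(hb$parent)), 1)
})

test_that("parent representative selection follows the rank-sum rule", {
  g <- make_group_seq(seed = 3)
  # single-member parent group: that marker, trivially
  h1 <- body_hierarchy(groups = list(parent = "P1",
                                     arm = c("A1", "A2", "A3", "A4"),
                                     rest = "P2"),
                       parents = list(arm = "parent", rest = "parent"))
  expect_equal(select_parent_representative(g$seq, h1, "arm"), "P1")

  # a rigid candidate at constant distance beats one with distance jitter
  set.seed(9)
  n <- n_frames(g$seq)
  pos <- g$seq$positions
  pos[, "P2", ] <- pos[, "P1", ] +
    matrix(rep(c(100, 0, 0), each = n), n) +
    20 * sin(2 * pi * 3 * seq_len(n) / 100) *
      matrix(rep(c(1, 1, 1) / sqrt(3), each = n), n)
  jittered <- mocap_sequence(pos, g$seq$labels, 100)
  # compute the two criteria directly as an oracle
  cen <- apply(jittered$positions[, c("A1", "A2", "A3", "A4"), ],
               c(1, 3), mean)
  sd_dist <- function(m) sd(sqrt(rowSums((marker_xyz(jittered, m) - cen)^2)))
  expect_lt(sd_dist("P1"), sd_dist("P2"))
  expect_equal(select_parent_representative(jittered, g$hier, "arm"), "P1")

  # identical candidates tie and break lexicographically
  pos2 <- g$seq$positions
  pos2[, "P2", ] <- pos2[, "P1", ]
  tied <- mocap_sequence(pos2, g$seq$labels, 100)
  expect_equal(select_parent_representative(tied, g$hier, "arm"), "P1")

  # deterministic across repeated calls
  expect_identical(select_parent_representative(g$seq, g$hier, "arm"),
                   select_parent_representative(g$seq, g$hier, "arm"))
  expect_error(select_parent_representative(g$seq, g$hier, "parent"),
               "root")
})
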