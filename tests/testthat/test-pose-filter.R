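test_that("catalytic distance is Euclidean with an inclusive 4 A boundary", {
  pose <- make_good_pose()                       # P1 C at (0,0,3.5)
  c1 <- check_catalytic_distance(pose)
  expect_equal(c1$distance, 3.5)
  expect_true(c1$pass)
  far <- make_pose(make_test_enzyme(),
                   make_test_substrate(p1c = c(0, 0, 4.2)),
                   catalytic_cys = 25, s2_residues = 67, s1p_residues = 140)
  expect_false(check_catalytic_distance(far)$pass)
  edge <- make_pose(make_test_enzyme(),
                    make_test_substrate(p1c = c(0, 0, 4.0)),
                    catalytic_cys = 25, s2_residues = 67, s1p_residues = 140)
  e1 <- check_catalytic_distance(edge)
  expect_equal(e1$distance, 4.0)
  expect_true(e1$pass)                           # "should not exceed"
})

test_that("distance equals a brute-force pairwise oracle", {
  set.seed(63)
  for (r in 1:10) {
    p1c <- runif(3, -8, 8)
    pose <- make_pose(make_test_enzyme(), make_test_substrate(p1c = p1c),
                      catalytic_cys = 25, s2_residues = 67,
                      s1p_residues = 140)
    sg <- unlist(pose$enzyme[pose$enzyme$elety == "SG", c("x", "y", "z")])
    expect_equal(check_catalytic_distance(pose)$distance,
                 sqrt(sum((sg - p1c)^2)))
  }
})

test_that("missing atoms give an unevaluable verdict, not a failure", {
  pose <- make_good_pose()
  pose$substrate <- pose$substrate[pose$substrate$elety != "C" |
                                     pose$substrate$plabel != "P1", ]
  c1 <- check_catalytic_distance(pose)
  expect_equal(c1$status, "unevaluable")
  expect_true(is.na(c1$pass))
})

test_that("orientation passes in-pocket geometry and fails reversed or
          distant substrates", {
  good <- make_good_pose()
  expect_true(check_orientation(good)$pass)
  # reversed substrate: P2 side chain in the S1' pocket and vice versa
  rev_sub <- make_test_substrate(p2_side = c(-5.5, 0, 1),
                                 p1p = c(5.5, 0, 1))
  reversed <- make_pose(make_test_enzyme(), rev_sub, catalytic_cys = 25,
                        s2_residues = 67, s1p_residues = 140)
  expect_false(check_orientation(reversed)$pass)
  # substrate 20 A away from the enzyme fails the contact threshold
  away <- make_pose(make_test_enzyme(),
                    make_test_substrate(p1c = c(20, 20, 20),
                                        p2_side = c(25, 20, 20),
                                        nter = c(26, 22, 21),
                                        p1p = c(15, 20, 20)),
                    catalytic_cys = 25, s2_residues = 67, s1p_residues = 140)
  expect_false(check_orientation(away)$pass)
  # unannotated subsites are unevaluable
  un <- make_pose(make_test_enzyme(), make_test_substrate(),
                  catalytic_cys = 25, s2_residues = integer(),
                  s1p_residues = 140)
  expect_true(is.na(check_orientation(un)$pass))
})

test_that("terminal accessibility counts enzyme atoms inclusively", {
  open <- make_good_pose()
  c3 <- check_terminal_accessibility(open)
  expect_true(c3$pass)
  # bury the N-terminus under a 30-atom cloud within 5 A
  nter <- c(6, 2, 2)
  cloud <- do.call(rbind, lapply(1:30, function(i) {
    data.frame(resno = 300 + i, resid = "GLY", elety = "CA",
               x = nter[1] + runif(1, -1, 1), y = nter[2] + runif(1, -1, 1),
               z = nter[3] + runif(1, -1, 1))
  }))
  buried <- make_pose(make_test_enzyme(extra = cloud), make_test_substrate(),
                      catalytic_cys = 25, s2_residues = 67,
                      s1p_residues = 140)
  cb <- check_terminal_accessibility(buried)
  expect_false(cb$pass)
  expect_gte(cb$n_count, 30)
  # counts exactly at burial_max still pass (inclusive boundary)
  expect_true(check_terminal_accessibility(buried,
                                           burial_max = cb$n_count)$pass)
})

test_that("burial counts are non-increasing as the radius shrinks", {
  set.seed(65)
  pose <- make_good_pose()
  radii <- c(8, 6, 5, 4, 3, 2)
  counts <- vapply(radii, function(r) {
    check_terminal_accessibility(pose, radius = r)$n_count
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("verdicts are invariant under joint rigid-body motion", {
  pose <- make_good_pose()
  v0 <- pose_verdict(pose)
  moved <- make_pose(apply_rigid(pose$enzyme), apply_rigid(pose$substrate),
                     catalytic_cys = 25, s2_residues = 67,
                     s1p_residues = 140)
  v1 <- pose_verdict(moved)
  expect_equal(v1$criterion1_distance, v0$criterion1_distance,
               tolerance = 1e-6)
  expect_identical(v1[, c("criterion1_pass", "criterion2_pass",
                          "criterion3_pass", "overall_pass")],
                   v0[, c("criterion1_pass", "criterion2_pass",
                          "criterion3_pass", "overall_pass")])
})

test_that("filter_poses reports survivors matching construction truth", {
  good <- make_good_pose()
  bad1 <- make_pose(make_test_enzyme(),
                    make_test_substrate(p1c = c(0, 0, 6)),
                    catalytic_cys = 25, s2_residues = 67, s1p_residues = 140)
  bad2 <- make_pose(make_test_enzyme(),
                    make_test_substrate(p2_side = c(-5.5, 0, 1),
                                        p1p = c(5.5, 0, 1)),
                    catalytic_cys = 25, s2_residues = 67, s1p_residues = 140)
  res <- filter_poses(list(g1 = good, b1 = bad1, b2 = bad2, g2 = good))
  expect_equal(res$verdicts$pose[res$survivors], c("g1", "g2"))
  expect_equal(res$status, "ok")
  all_good <- filter_poses(rep(list(good), 10))
  expect_length(all_good$survivors, 10)
  # all-unevaluable input is distinct from "0 passed"
  un <- make_pose(make_test_enzyme(), make_test_substrate(),
                  catalytic_cys = 999, s2_residues = integer(),
                  s1p_residues = integer())
  res_un <- filter_poses(list(un, un))
  expect_equal(res_un$status, "no_evaluable")
  expect_length(res_un$survivors, 0)
})

test_that("poses survive a PDB round-trip through bio3d", {
  pose <- make_good_pose()
  tmp <- tempfile(fileext = ".pdb")
  at <- rbind(cbind(pose$enzyme, chain = "A"),
              cbind(pose$substrate[, names(pose$enzyme)], chain = "B"))
  bio3d::write.pdb(file = tmp, xyz = as.numeric(t(as.matrix(
    at[, c("x", "y", "z")]))), resno = at$resno, resid = at$resid,
    elety = at$elety, chain = at$chain)
  back <- read_pose_pdb(tmp, list(catalytic_cys = 25, s2_residues = 67,
                                  s1p_residues = 140))
  v <- pose_verdict(back)
  expect_true(v$overall_pass)
  expect_equal(v$criterion1_distance, 3.5, tolerance = 1e-3)
})
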