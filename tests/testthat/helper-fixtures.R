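# Shared fixture builders. All randomness is locally seeded so individual
# test files are order-independent.

random_rotation <- function() {
  # QR of a Gaussian matrix with determinant sign fix: Haar-ish, always proper
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_rigid <- function(source_frame = "a", target_frame = "b",
                         trans_scale = 50) {
  rigid_transform(random_rotation(), rnorm(3, 0, trans_scale),
                  source_frame, target_frame)
}

random_landmarks <- function(n = 6, spread = 60) {
  matrix(runif(3 * n, -spread, spread), n, 3)
}

# a simple well-formed screw for unit tests
fixture_screw <- function(head = c(0, 0, 0), tip = c(0, 0, 45),
                          length_mm = NULL, diameter_mm = 6.5,
                          frame = "navCT", case_id = "C1", screw_id = "s1",
                          level = "L4", side = "left", role = "planned") {
  if (is.null(length_mm)) length_mm <- sqrt(sum((tip - head)^2))
  screw(case_id, screw_id, level, side, role, head, tip,
        diameter_mm, length_mm, frame)
}
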