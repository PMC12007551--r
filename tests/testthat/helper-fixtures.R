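## Small fixtures built in code.

## straight cable along -z starting at the origin
straight_cable <- function(length_um = 100, diam = 2, kind = "dendrite",
                           n_pts = 2) {
  zs <- seq(0, -length_um, length.out = n_pts)
  pts <- cbind(0, 0, zs)
  morphology(list(section(kind, pts, rep(diam, n_pts), NA)),
             identifier = "cable")
}

## cable along +z (for sign-convention checks)
up_cable <- function(length_um = 100, diam = 2, kind = "dendrite") {
  pts <- rbind(c(0, 0, 0), c(0, 0, length_um))
  morphology(list(section(kind, pts, rep(diam, 2), NA)), identifier = "upcable")
}

## mirror-symmetric Y: vertical stem down, two branches mirrored in x
y_morphology <- function(stem = 200, branch = 200, diam = 2,
                         kind = "dendrite") {
  s1 <- section(kind, rbind(c(0, 0, 0), c(0, 0, -stem)), rep(diam, 2), NA)
  tip <- c(0, 0, -stem)
  b <- branch / sqrt(2)
  s2 <- section(kind, rbind(tip, tip + c(b, 0, -b)), rep(diam, 2), 1L)
  s3 <- section(kind, rbind(tip, tip + c(-b, 0, -b)), rep(diam, 2), 1L)
  morphology(list(s1, s2, s3), identifier = "ycell")
}

## a small excitable cell with a fast, well-behaved threshold
small_active_cell <- function(axon_length = 300, axon_diameter = 2)
  generate_ball_and_stick(axon_length, axon_diameter, soma_diameter = 12)

## constant-on step "waveform" (unit amplitude over the whole window)
step_waveform <- function(dt = 5, duration = 1000)
  make_waveform("custom", dt = dt, duration = duration,
                samples = rep(1, floor(duration / dt) + 1L))

## closed-form quasipotential for a uniform field: -E . (r - r_root), mV
uniform_phi_oracle <- function(cm, Evec) {
  dr <- sweep(cm$center, 2, cm$center[1, ])
  -(dr %*% Evec) * 1e-3
}

expect_tms_error <- function(expr, class) {
  expect_error(expr, class = class)
}

section_length_for_test <- function(s) {
  pts <- s$points
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums((pts[-1L, , drop = FALSE] -
                      pts[-nrow(pts), , drop = FALSE])^2)))
}
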