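# Canonical synthetic systems used for validation and examples. The
# geometry (lengths per timepoint, radii, emergence pattern) mirrors the
# hand-measured three-timepoint validation models: a straight primary
# axis growing from 63.8 to 95.2 mm with six laterals of radii
# 1.0/0.885/0.685 mm appearing over three acquisitions.

#' Straight single-branch system
#'
#' One ball of radius `radius` swept along a straight vertical segment:
#' the simplest fixture, with known tortuosity exactly 1 and vertical
#' orientation.
#'
#' @param length segment length in mm.
#' @param radius sweep radius in mm.
#' @return list of one [branch_spec()].
#' @export
straight_root_spec <- function(length = 63.8, radius = 1.5) {
  list(branch_spec("r0", rbind(c(0, 0, 0), c(0, 0, -length - 1)),
                   radius = radius, appear = 0L,
                   schedule = length))
}

#' Three-timepoint multi-branch validation system
#'
#' A caricature of a growing cereal root system: a straight primary and
#' six curved laterals whose per-timepoint lengths follow the
#' hand-measured validation series (four branches at t = 0, six at t = 1,
#' seven at t = 2; primary 63.8 / 71.1 / 95.2 mm). Pass to
#' [generate_series()] with `T = 2`, `edge_length = 0.5` and a seed ball
#' of 4 mm to reproduce the standard fixture.
#'
#' @return list of [branch_spec()] objects.
#' @export
validation_root_system <- function() {
  list(
    branch_spec("r0", rbind(c(0, 0, 0), c(0, 0, -100)),
                radius = 1.5, appear = 0L,
                schedule = c(63.80, 71.10, 95.22)),
    branch_spec("r1",
                rbind(c(0, 0, 0), c(26.8, 2, -29.7), c(50, 3, -62),
                      c(66, 2, -100)),
                radius = 1.0, appear = 0L,
                schedule = c(35.77, 76.11, 102.68),
                parent = "r0", attach_s = 8),
    branch_spec("r2",
                rbind(c(0, 0, 0), c(-33, -2, -23), c(-60, -4, -50),
                      c(-78, -3, -85)),
                radius = 1.0, appear = 0L,
                schedule = c(42.98, 66.77, 99.06),
                parent = "r0", attach_s = 12),
    branch_spec("r6",
                rbind(c(0, 0, 0), c(2, 23, -19), c(3, 42, -42),
                      c(2, 55, -68)),
                radius = 1.0, appear = 0L,
                schedule = c(27.49, 35.01, 53.73),
                parent = "r0", attach_s = 20),
    branch_spec("r3",
                rbind(c(0, 0, 0), c(-2, -20, -20), c(-3, -36, -44)),
                radius = 0.885, appear = 1L,
                schedule = c(7.00, 37.55),
                parent = "r0", attach_s = 30),
    branch_spec("r5",
                rbind(c(0, 0, 0), c(10, -12, -13), c(20, -22, -28)),
                radius = 0.685, appear = 1L,
                schedule = c(4.30, 27.83),
                parent = "r0", attach_s = 38),
    branch_spec("r4",
                rbind(c(0, 0, 0), c(-5, 5, -7), c(-10, 10, -15)),
                radius = 0.685, appear = 2L,
                schedule = c(9.27),
                parent = "r0", attach_s = 50)
  )
}

#' Small three-branch system for registration studies
#'
#' A compact nested-growth system (primary plus two laterals over three
#' timepoints) used where many seeded replicates are run, e.g. to measure
#' motion-recovery statistics.
#'
#' @return list of [branch_spec()] objects.
#' @export
small_root_system <- function() {
  # deliberately asymmetric (both laterals on the same half-space, with
  # different angles, lengths and radii) so rigid registration has a
  # unique optimum
  list(
    branch_spec("a", rbind(c(0, 0, 0), c(3, 1, -20), c(2, -2, -45),
                           c(6, 0, -62)),
                radius = 1.5, appear = 0L, schedule = c(35, 45, 58)),
    branch_spec("b", rbind(c(0, 0, 0), c(13, 4, -12), c(25, 6, -26)),
                radius = 1.0, appear = 0L, schedule = c(18, 26, 35),
                parent = "a", attach_s = 7),
    branch_spec("c", rbind(c(0, 0, 0), c(4, 9, -14), c(6, 14, -30)),
                radius = 0.7, appear = 1L, schedule = c(10, 22),
                parent = "a", attach_s = 18)
  )
}

#' Curved single-branch systems with known tortuosity
#'
#' Circular arcs (in a vertical plane, starting straight down and
#' curving away) and descending helices. Their arc length and chord - and
#' hence tortuosity - follow from the generating curve.
#'
#' @return list of lists of [branch_spec()]; one single-branch system per
#'   element, covering arcs of 50, 70 and 90 degrees and two helices.
#' @export
curved_branch_specs <- function() {
  arc <- function(name, Rc, phi_max_deg, n = 24L) {
    phi <- seq(0, phi_max_deg * pi / 180, length.out = n)
    ctrl <- cbind(Rc * (1 - cos(phi)), 0, -Rc * sin(phi))
    list(branch_spec(name, ctrl, radius = 1.25, appear = 0L,
                     schedule = 0.95 * Rc * max(phi)))
  }
  helix <- function(name, a, pitch, turns, n = 40L) {
    th <- seq(0, 2 * pi * turns, length.out = n)
    ctrl <- cbind(a * cos(th) - a, a * sin(th), -pitch * th / (2 * pi))
    total <- sqrt(a^2 + (pitch / (2 * pi))^2) * max(th)
    list(branch_spec(name, ctrl, radius = 1.25, appear = 0L,
                     schedule = 0.95 * total))
  }
  list(
    arc50 = arc("arc50", Rc = 70, phi_max_deg = 50),
    arc70 = arc("arc70", Rc = 55, phi_max_deg = 70),
    arc90 = arc("arc90", Rc = 45, phi_max_deg = 90),
    helix1 = helix("helix1", a = 8, pitch = 55, turns = 0.9),
    helix2 = helix("helix2", a = 11, pitch = 45, turns = 1.25)
  )
}
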