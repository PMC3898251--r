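#' Ideal covalent geometry of an engineered cystine
#'
#' Bond lengths and angles used when modeling cysteine side chains from
#' backbone coordinates. These follow standard cystine stereochemistry;
#' they are configuration, not hard-wired constants, so users working with
#' non-standard force-field geometry can override any of them.
#'
#' @param d_ca_cb CA-CB bond length, Angstrom.
#' @param d_cb_sg CB-SG bond length, Angstrom.
#' @param d_ss SG-SG disulfide bond length, Angstrom.
#' @param ang_ca_cb_sg CA-CB-SG bond angle, degrees.
#' @param ang_cb_s_s CB-SG-SG' bond angle, degrees.
#'
#' @return An object of class `ideal_params` (a named list).
#' @export
#' @examples
#' ideal_params()
#' ideal_params(d_ss = 2.05)
ideal_params <- function(d_ca_cb = 1.53, d_cb_sg = 1.81, d_ss = 2.04,
                         ang_ca_cb_sg = 114.6, ang_cb_s_s = 104.9) {
  p <- list(d_ca_cb = d_ca_cb, d_cb_sg = d_cb_sg, d_ss = d_ss,
            ang_ca_cb_sg = ang_ca_cb_sg, ang_cb_s_s = ang_cb_s_s)
  for (d in c("d_ca_cb", "d_cb_sg", "d_ss"))
    if (!is.numeric(p[[d]]) || length(p[[d]]) != 1L || p[[d]] <= 0)
      stop("ideal_params: '", d, "' must be a single positive distance")
  for (a in c("ang_ca_cb_sg", "ang_cb_s_s"))
    if (!is.numeric(p[[a]]) || length(p[[a]]) != 1L || p[[a]] <= 0 || p[[a]] >= 180)
      stop("ideal_params: '", a, "' must be an angle in (0, 180) degrees")
  structure(p, class = "ideal_params")
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-10) stop("degenerate geometry: zero-length ", what)
  v / n
}

check_point <- function(p, nm) {
  if (!is.numeric(p) || length(p) != 3L || any(!is.finite(p)))
    stop("'", nm, "' must be a finite numeric 3-vector")
  as.numeric(p)
}

#' Euclidean distance between two points
#'
#' @param p1,p2 Numeric 3-vectors, Angstrom.
#' @return Distance in Angstrom.
#' @export
vec_distance <- function(p1, p2) {
  vnorm(check_point(p2, "p2") - check_point(p1, "p1"))
}

#' Bond angle at a vertex
#'
#' Angle p1-p2-p3 with the vertex at `p2`.
#'
#' @param p1,p2,p3 Numeric 3-vectors, Angstrom.
#' @return Angle in degrees, in \[0, 180\].
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- unitv(check_point(p1, "p1") - check_point(p2, "p2"), "p2->p1 bond")
  v <- unitv(check_point(p3, "p3") - check_point(p2, "p2"), "p2->p3 bond")
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Signed dihedral (torsion) angle
#'
#' Torsion of the four points p1-p2-p3-p4 about the p2-p3 axis, using the
#' standard atan2 convention: looking down p2 to p3, a positive angle is a
#' clockwise rotation of p4 relative to p1. This is the convention under
#' which native disulfide chi3 torsions cluster near -87 and +97 degrees.
#' The torsion is invariant under reversal of the point order and negates
#' under mirror reflection.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors, Angstrom.
#' @return Angle in degrees in (-180, 180].
#' @export
#' @examples
#' dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)) # +90
dihedral <- function(p1, p2, p3, p4) {
  p1 <- check_point(p1, "p1"); p2 <- check_point(p2, "p2")
  p3 <- check_point(p3, "p3"); p4 <- check_point(p4, "p4")
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("degenerate geometry: collinear or coincident points in dihedral()")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / vnorm(b2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from internal coordinates
#'
#' Natural-extension-reference-frame placement: returns the point p4 at
#' distance `r` from p3, bond angle p2-p3-p4 equal to `theta`, and torsion
#' p1-p2-p3-p4 equal to `phi` (both degrees, under the [dihedral()]
#' convention).
#'
#' @param p1,p2,p3 Reference points (3-vectors, Angstrom).
#' @param r Bond length p3-p4, Angstrom.
#' @param theta Bond angle p2-p3-p4, degrees.
#' @param phi Torsion p1-p2-p3-p4, degrees. May be a vector, in which case
#'   a matrix with one row per torsion value is returned.
#' @return A 3-vector, or an `length(phi)` x 3 matrix when `phi` is a vector.
#' @export
place_atom <- function(p1, p2, p3, r, theta, phi) {
  p1 <- check_point(p1, "p1"); p2 <- check_point(p2, "p2")
  p3 <- check_point(p3, "p3")
  b1 <- p2 - p1; b2 <- p3 - p2
  u2 <- unitv(b2, "p2->p3 bond")
  nz <- cross3(b1, b2)
  if (vnorm(nz) < 1e-10)
    stop("degenerate geometry: collinear reference points in place_atom()")
  nz <- nz / vnorm(nz)
  m <- cross3(nz, u2)
  th <- deg2rad(theta); ph <- deg2rad(phi)
  ax <- -cos(th)
  ay <- sin(th) * cos(ph)
  az <- sin(th) * sin(ph)
  if (length(phi) == 1L)
    return(p3 + r * (ax * u2 + ay * m + az * nz))
  out <- cbind(ax * u2[1L] + ay * m[1L] + az * nz[1L],
               ax * u2[2L] + ay * m[2L] + az * nz[2L],
               ax * u2[3L] + ay * m[3L] + az * nz[3L])
  sweep(r * out, 2L, p3, "+")
}

#' Reconstruct an idealized beta carbon from backbone atoms
#'
#' Places CB at distance `params$d_ca_cb` from CA, with tetrahedral bond
#' angles N-CA-CB and C-CA-CB of 110.5 degrees, on the side consistent with
#' L-amino-acid chirality (the improper torsion N-CA-C-CB is about -122.5
#' degrees under the [dihedral()] convention, as measured in crystal
#' structures of L-proteins). Used to make glycine and missing-side-chain
#' residues uniform with the rest of the chain during scanning.
#'
#' @param n,ca,c Backbone N, CA, C coordinates (3-vectors, Angstrom).
#' @param params An [ideal_params()] object.
#' @return The CB coordinate (3-vector, Angstrom).
#' @export
construct_cbeta <- function(n, ca, c, params = ideal_params()) {
  n <- check_point(n, "n"); ca <- check_point(ca, "ca"); c <- check_point(c, "c")
  u <- unitv(n - ca, "CA->N bond")
  v <- unitv(c - ca, "CA->C bond")
  w <- cross3(u, v)
  wn <- vnorm(w)
  if (wn < 1e-8)
    stop("degenerate geometry: collinear backbone atoms in construct_cbeta()")
  ct <- cos(deg2rad(110.5))
  s <- u + v
  a <- ct / (1 + sum(u * v))        # coefficient on the bisector
  b2 <- (1 - a^2 * sum(s * s)) / wn^2
  if (b2 < 1e-12)
    stop("degenerate geometry: backbone angle incompatible with a tetrahedral CB")
  b <- sqrt(b2)
  # two mirror solutions; keep the L-chirality branch (improper < 0)
  for (sgn in c(-1, 1)) {
    d <- a * s + sgn * b * w
    cb <- ca + params$d_ca_cb * d / vnorm(d)
    if (dihedral(n, ca, c, cb) < 0) return(cb)
  }
  stop("construct_cbeta: failed to resolve chirality (degenerate input)")
}

#' Model a cysteine SG position as a function of chi1
#'
#' Forward kinematics of the cysteine side chain: SG is placed at distance
#' `params$d_cb_sg` from CB, bond angle CA-CB-SG equal to
#' `params$ang_ca_cb_sg`, and torsion N-CA-CB-SG equal to `chi1`.
#'
#' @param n,ca,cb N, CA and CB coordinates (3-vectors, Angstrom).
#' @param chi1 Side-chain torsion N-CA-CB-SG, degrees. May be a vector.
#' @param params An [ideal_params()] object.
#' @return SG coordinate: a 3-vector, or a matrix (one row per `chi1`).
#' @export
place_sgamma <- function(n, ca, cb, chi1, params = ideal_params()) {
  place_atom(n, ca, cb, params$d_cb_sg, params$ang_ca_cb_sg, chi1)
}

#' @export
print.ideal_params <- function(x, ...) {
  cat("Ideal cystine geometry:\n")
  cat(sprintf("  CA-CB %.3f A, CB-SG %.3f A, SG-SG %.3f A\n",
              x$d_ca_cb, x$d_cb_sg, x$d_ss))
  cat(sprintf("  CA-CB-SG %.1f deg, CB-SG-SG' %.1f deg\n",
              x$ang_ca_cb_sg, x$ang_cb_s_s))
  invisible(x)
}
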