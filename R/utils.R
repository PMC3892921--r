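#' @keywords internal
"_PACKAGE"

# Condition helpers: input errors (bad user-supplied data) are distinguished
# from runtime failures so the CLI can map them to distinct exit codes.
cm_input_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cleftmatch_input_error", "cleftmatch_error")))
}

cm_runtime_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cleftmatch_runtime_error", "cleftmatch_error")))
}

cm_warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

extdata <- function(file) {
  path <- system.file("extdata", file, package = "cleftmatch")
  if (!nzchar(path)) cm_runtime_error("missing packaged data file '%s'", file)
  path
}

# Euclidean distance matrix between the rows of two n x 3 coordinate matrices.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

pair_dist <- function(xyz) cross_dist(xyz, xyz)

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# Van der Waals radii (Angstrom) used by the gap-sphere cleft detector.
VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)
VDW_DEFAULT <- 1.7

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

# Covalent radii (Angstrom) for distance-based bond perception.
COV_RADII <- c(C = 0.77, N = 0.75, O = 0.73, S = 1.02, P = 1.06, H = 0.37,
               F = 0.71, CL = 0.99, BR = 1.14, I = 1.33, SE = 1.17, B = 0.82,
               SI = 1.11, FE = 1.25, ZN = 1.25, MG = 1.3, MN = 1.35, "NA" = 1.54,
               K = 1.96, CA = 1.74, CU = 1.28, NI = 1.21, CO = 1.26)
COV_DEFAULT <- 1.1
BOND_TOL <- 0.45

covalent_radius <- function(element) {
  r <- COV_RADII[toupper(element)]
  r[is.na(r)] <- COV_DEFAULT
  unname(r)
}
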