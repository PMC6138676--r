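# Coordinate-ensemble statistics: Kabsch superposition, RMSD, RMSF, radius
# of gyration, and PCA of the positional covariance (essential dynamics).
# Coordinates are nm everywhere; PDB I/O converts from Angstrom.

#' Coordinate ensemble container
#'
#' @param coords Numeric array n_frames x n_atoms x 3 (nm). A single
#'   n_atoms x 3 matrix is promoted to a 1-frame ensemble.
#' @param atoms Atom annotation data frame with `resno`, `elety`, `resid`
#'   (one row per atom); defaults to sequentially numbered CA atoms.
#' @return Object of class `coord_ensemble`.
#' @export
coord_ensemble <- function(coords, atoms = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1, dim(coords)))
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[1] >= 1, all(is.finite(coords)))
  n_at <- dim(coords)[2]
  if (is.null(atoms))
    atoms <- data.frame(resno = seq_len(n_at), elety = "CA", resid = "ALA")
  stopifnot(nrow(atoms) == n_at)
  structure(list(coords = coords, atoms = atoms), class = "coord_ensemble")
}

#' @export
print.coord_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("coordinate ensemble: %d frame(s) x %d atoms (nm)\n", d[1], d[2]))
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param x A `coord_ensemble`.
#' @name ensemble-dims
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname ensemble-dims
#' @export
n_atoms <- function(x) dim(x$coords)[2]

# f-th frame as an n_atoms x 3 matrix
.frame <- function(x, f) matrix(x$coords[f, , ], ncol = 3)

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares rotation and translation mapping `mobile` onto `target`,
#' with a proper rotation enforced (determinant +1 by sign correction of
#' the smallest singular direction).
#'
#' @param mobile,target n_atoms x 3 coordinate matrices (>= 3 non-collinear
#'   atoms, equal counts).
#' @param weights Optional per-atom weights (>= 0, not all zero).
#' @return List with `rotation` (3 x 3, applied on the right of centered
#'   row-vector coordinates), `translation`, `rmsd` (weighted RMS deviation
#'   after superposition, nm), and `coords` (the superposed mobile).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3, all(dim(mobile) == dim(target)),
            nrow(mobile) >= 3)
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); ct <- colSums(target * w)
  p <- sweep(mobile, 2, cm); q <- sweep(target, 2, ct)
  if (svd(p)$d[2] < 1e-10 * max(1, svd(p)$d[1]))
    stop("degenerate (collinear) atom configuration")
  h <- crossprod(p * w, q)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- p %*% rot
  rmsd <- sqrt(sum(w * rowSums((fitted - q)^2)))
  list(rotation = rot, translation = ct - cm %*% rot, rmsd = rmsd,
       coords = sweep(fitted, 2, ct, FUN = "+"))
}

#' Per-frame RMSD of an ensemble against a reference
#'
#' Each frame is Kabsch-superposed onto the reference before the deviation
#' is measured.
#'
#' @param ensemble A [coord_ensemble()].
#' @param reference Frame index into the ensemble (default 1) or an
#'   external n_atoms x 3 matrix.
#' @param window Optional index range over which the mean RMSD is reported
#'   (attribute `mean`); default all frames.
#' @return Numeric vector of per-frame RMSDs (nm) with attribute `mean`.
#' @export
rmsd_series <- function(ensemble, reference = 1, window = NULL) {
  stopifnot(inherits(ensemble, "coord_ensemble"))
  ref <- if (is.matrix(reference)) reference else .frame(ensemble, reference)
  stopifnot(nrow(ref) == n_atoms(ensemble))
  r <- vapply(seq_len(n_frames(ensemble)), function(f)
    kabsch_superpose(.frame(ensemble, f), ref)$rmsd, numeric(1))
  if (is.null(window)) window <- seq_along(r)
  attr(r, "mean") <- mean(r[window])
  r
}

# Align all frames onto the ensemble mean structure, with one refinement
# iteration (mean -> superpose -> recompute mean -> superpose). Returns the
# aligned coordinate array and the final mean.
.align_to_mean <- function(ensemble) {
  co <- ensemble$coords
  nf <- dim(co)[1]
  for (pass in 1:2) {
    m <- apply(co, c(2, 3), mean)
    for (f in seq_len(nf))
      co[f, , ] <- kabsch_superpose(matrix(co[f, , ], ncol = 3), m)$coords
  }
  list(coords = co, mean = apply(co, c(2, 3), mean))
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames are superposed onto the ensemble mean structure (one refinement
#' iteration), then RMSF_i = sqrt(mean over frames |r_i - <r_i>|^2).
#'
#' @param ensemble A [coord_ensemble()] with >= 2 frames.
#' @return Numeric vector, one RMSF per atom (nm).
#' @export
rmsf <- function(ensemble) {
  stopifnot(inherits(ensemble, "coord_ensemble"))
  if (n_frames(ensemble) < 2) stop("RMSF needs at least 2 frames")
  al <- .align_to_mean(ensemble)
  dev2 <- sweep(al$coords, c(2, 3), al$mean)^2
  sqrt(rowSums(apply(dev2, c(2, 3), mean)))
}

# standard atomic masses by element symbol; unknown elements fall back to
# unit masses for the whole selection
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06)

.masses_from_atoms <- function(atoms) {
  el <- toupper(substr(gsub("[^A-Za-z].*", "", atoms$elety), 1, 1))
  m <- .atomic_masses[el]
  if (any(is.na(m))) return(rep(1, nrow(atoms)))
  unname(m)
}

#' Radius of gyration per frame
#'
#' Rg = sqrt(sum m_i |r_i - r_com|^2 / sum m_i). Mass-weighted by default
#' using standard atomic masses inferred from atom names; unit masses are
#' used when any element is unrecognized, or pass `masses` explicitly.
#'
#' @param ensemble A [coord_ensemble()] (or n_atoms x 3 matrix).
#' @param masses Optional per-atom masses (> 0 total).
#' @return Numeric vector of per-frame Rg (nm) with attribute `mean`.
#' @export
radius_of_gyration <- function(ensemble, masses = NULL) {
  if (is.matrix(ensemble)) ensemble <- coord_ensemble(ensemble)
  stopifnot(inherits(ensemble, "coord_ensemble"))
  if (is.null(masses)) masses <- .masses_from_atoms(ensemble$atoms)
  stopifnot(length(masses) == n_atoms(ensemble), sum(masses) > 0,
            all(masses >= 0))
  w <- masses / sum(masses)
  rg <- vapply(seq_len(n_frames(ensemble)), function(f) {
    x <- .frame(ensemble, f)
    com <- colSums(x * w)
    sqrt(sum(w * rowSums(sweep(x, 2, com)^2)))
  }, numeric(1))
  attr(rg, "mean") <- mean(rg)
  rg
}

#' Principal component analysis of the positional covariance
#'
#' Frames are superposed onto the ensemble mean (as in [rmsf()]), the
#' 3N x 3N covariance of the selected atoms' coordinates about their mean
#' is eigendecomposed, and eigenvalues are reported in descending order
#' with their variance fractions. Leading eigenvectors are the dominant
#' collective motions (essential dynamics).
#'
#' @param ensemble A [coord_ensemble()] with > 3 frames.
#' @param selection `"calpha"` (default; falls back to all atoms when no CA
#'   atoms are annotated) or `"all"`, or a logical/integer atom index.
#' @return Object of class `pca_ensemble`: `values` (nm^2, descending),
#'   `vectors` (3N x k, orthonormal, atom-major xyz layout), `fractions`,
#'   `projections` (frames x k), `mean` (selected-atom mean structure),
#'   `atoms` (selected annotation).
#' @export
pca_ensemble <- function(ensemble, selection = "calpha") {
  stopifnot(inherits(ensemble, "coord_ensemble"))
  if (n_frames(ensemble) <= 3) stop("PCA needs more than 3 frames")
  idx <- if (is.character(selection)) {
    selection <- match.arg(selection, c("calpha", "all"))
    if (selection == "calpha" && any(ensemble$atoms$elety == "CA"))
      which(ensemble$atoms$elety == "CA")
    else seq_len(n_atoms(ensemble))
  } else if (is.logical(selection)) which(selection) else as.integer(selection)
  sub <- coord_ensemble(ensemble$coords[, idx, , drop = FALSE],
                        atoms = ensemble$atoms[idx, , drop = FALSE])
  al <- .align_to_mean(sub)
  nf <- dim(al$coords)[1]
  # frames x 3N, atom-major xyz within atom
  x <- t(vapply(seq_len(nf),
                function(f) as.numeric(t(matrix(al$coords[f, , ], ncol = 3))),
                numeric(3 * length(idx))))
  xc <- sweep(x, 2, colMeans(x))
  cv <- crossprod(xc) / (nf - 1)
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  structure(list(values = vals, vectors = e$vectors,
                 fractions = vals / sum(vals),
                 projections = xc %*% e$vectors, mean = al$mean,
                 atoms = sub$atoms, trace = sum(diag(cv))),
            class = "pca_ensemble")
}

#' @export
print.pca_ensemble <- function(x, ...) {
  cat(sprintf("ensemble PCA: %d modes; PC1-3 variance fractions %s\n",
              length(x$values),
              paste(sprintf("%.1f%%", 100 * x$fractions[1:min(3, length(x$values))]),
                    collapse = ", ")))
  invisible(x)
}

#' Export a principal component as a two-model porcupine structure
#'
#' Model 1 is the mean structure; model 2 is the mean displaced by
#' scale * sqrt(eigenvalue) along the chosen eigenvector, so any viewer can
#' draw per-atom arrows between paired atoms of the two models.
#'
#' @param pca A [pca_ensemble()] result.
#' @param component Component index (within the result).
#' @param scale Displacement scale in units of the mode's SD.
#' @param file Output PDB path.
#' @return Invisibly, a list with `mean` and `displaced` coordinate
#'   matrices (nm); the PDB on disk is in Angstrom.
#' @export
porcupine_export <- function(pca, component = 1, scale = 2, file) {
  stopifnot(inherits(pca, "pca_ensemble"),
            component >= 1, component <= length(pca$values))
  lam <- pca$values[component]
  if (lam <= 0 && scale != 0) {
    warning("zero-eigenvalue component requested; models will be identical")
    lam <- 0
  }
  disp <- matrix(pca$vectors[, component], ncol = 3, byrow = TRUE) *
    scale * sqrt(lam)
  displaced <- pca$mean + disp
  xyz <- rbind(as.numeric(t(pca$mean)) * 10, as.numeric(t(displaced)) * 10)
  bio3d::write.pdb(file = file, xyz = xyz, resno = pca$atoms$resno,
                   resid = pca$atoms$resid, elety = pca$atoms$elety)
  invisible(list(mean = pca$mean, displaced = displaced))
}
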