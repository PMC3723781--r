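#' Ideal backbone geometry constants
#'
#' Fixed bond lengths and angles used for internal-to-Cartesian chain
#' building. Defaults are standard Engh–Huber-like values; they give the
#' familiar ~3.8 A CA(i)–CA(i+1) spacing for a trans peptide.
#'
#' @param n_ca,ca_c,c_n bond lengths in Angstrom.
#' @param n_ca_c,ca_c_n,c_n_ca bond angles in degrees (angle at CA, C, N).
#' @return an object of class `ideal_geometry` with `bonds` and `angles`
#'   vectors in the order the chain builder consumes them.
#' @export
ideal_geometry <- function(n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
                           n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7) {
  bonds <- c(n_ca = n_ca, ca_c = ca_c, c_n = c_n)
  angles <- c(n_ca_c = n_ca_c, ca_c_n = ca_c_n, c_n_ca = c_n_ca)
  if (any(bonds <= 0) || any(angles <= 0)) stop("geometry must be positive")
  structure(list(bonds = bonds, angles = angles), class = "ideal_geometry")
}

.valid_aa <- function(sequence) {
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(toupper(sequence), "")[[1]]
  all(chars %in% letters20)
}

#' Build backbone coordinates from torsions
#'
#' Deterministic internal-to-Cartesian construction (NeRF) under ideal
#' geometry. The first residue is placed in a fixed canonical frame (N at the
#' origin, CA on +x, C in the xy plane), so equal torsions give bitwise-equal
#' coordinates. Measuring dihedrals from the result with
#' [measure_torsions()] recovers the input.
#'
#' @param torsions n x 3 numeric matrix of (phi, psi, omega) in degrees.
#' @param geometry an [ideal_geometry].
#' @return 3n x 3 coordinate matrix, atom order N, CA, C per residue.
#' @export
build_coords <- function(torsions, geometry = ideal_geometry()) {
  torsions <- as.matrix(torsions)
  if (ncol(torsions) != 3L) stop("torsions must be an n x 3 matrix")
  build_backbone_cpp(torsions, geometry$bonds, geometry$angles)
}

#' Measure backbone dihedrals from coordinates
#'
#' Inverse of [build_coords()]: per-residue (phi, psi, omega) in degrees from
#' a 3n x 3 backbone matrix. phi of the first residue and psi/omega of the
#' last are undefined and returned as `NA`.
#'
#' @param coords 3n x 3 backbone coordinate matrix (N, CA, C per residue).
#' @return n x 3 matrix with columns phi, psi, omega.
#' @export
measure_torsions <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) %% 3L != 0L) stop("coords must have 3 atoms per residue")
  out <- canonicalize_torsion(measure_torsions_cpp(coords))
  colnames(out) <- c("phi", "psi", "omega")
  out
}

.new_conformation <- function(sequence, torsions, geometry, coords,
                              provenance9, provenance3) {
  structure(list(sequence = sequence, torsions = torsions,
                 geometry = geometry, coords = coords,
                 provenance9 = provenance9, provenance3 = provenance3),
            class = "conformation")
}

#' Construct a conformation from torsions
#'
#' A conformation is the torsion-space backbone model: sequence, per-residue
#' (phi, psi, omega), derived Cartesian N/CA/C coordinates, and the fragment
#' provenance maps recording which library fragment currently occupies each
#' window (9-mer and 3-mer tracked separately).
#'
#' @param sequence amino-acid string.
#' @param torsions n x 3 matrix of torsions in degrees (canonicalized).
#' @param geometry an [ideal_geometry].
#' @return an object of class `conformation`.
#' @export
conformation <- function(sequence, torsions, geometry = ideal_geometry()) {
  n <- nchar(sequence)
  torsions <- as.matrix(torsions)
  if (nrow(torsions) != n)
    stop("torsions rows (", nrow(torsions), ") != sequence length (", n, ")")
  if (!.valid_aa(sequence)) stop("invalid amino-acid sequence")
  torsions <- canonicalize_torsion(torsions)
  colnames(torsions) <- c("phi", "psi", "omega")
  coords <- build_coords(torsions, geometry)
  prov <- setNames(integer(0), character(0))
  .new_conformation(toupper(sequence), torsions, geometry, coords, prov, prov)
}

#' Extended starting conformation
#'
#' Every model build starts from the extended state: phi = -150, psi = +150,
#' omega = 180 degrees at every residue, with empty fragment provenance.
#'
#' @param sequence amino-acid string, length >= 9.
#' @param geometry an [ideal_geometry].
#' @return a `conformation`.
#' @export
extended_conformation <- function(sequence, geometry = ideal_geometry()) {
  n <- nchar(sequence)
  if (n < 9L) stop("sequence must have at least 9 residues")
  torsions <- cbind(phi = rep(-150, n), psi = rep(150, n),
                    omega = rep(180, n))
  conformation(sequence, torsions, geometry)
}

#' @export
print.conformation <- function(x, ...) {
  cat("Backbone conformation:", nchar(x$sequence), "residues,",
      length(x$provenance9), "nine-mer and", length(x$provenance3),
      "three-mer windows with recorded fragment provenance\n")
  invisible(x)
}

#' CA coordinates of a conformation or backbone matrix
#'
#' @param x a `conformation` or a 3n x 3 backbone coordinate matrix.
#' @return n x 3 matrix of alpha-carbon coordinates.
#' @export
ca_coords <- function(x) {
  coords <- if (inherits(x, "conformation")) x$coords else as.matrix(x)
  coords[seq(2L, nrow(coords), by = 3L), , drop = FALSE]
}

# Last-writer-wins provenance bookkeeping: recording fragment `frag_index`
# at `start` invalidates any other same-length window whose residue range
# overlaps the insertion. `prov` is a named integer vector keyed by window
# start.
.update_provenance <- function(prov, start, len, frag_index) {
  if (length(prov)) {
    starts <- as.integer(names(prov))
    keep <- abs(starts - start) >= len
    prov <- prov[keep]
  }
  prov[[as.character(start)]] <- as.integer(frag_index)
  prov
}

#' Insert a fragment into a conformation
#'
#' Replaces the torsions of residues `start..start+len-1` with the chosen
#' fragment's torsions, rebuilds the Cartesian coordinates, and updates the
#' provenance map for that fragment length: the inserted window records
#' `frag_index`, and any same-length window overlapping the insertion loses
#' its provenance (it has been partially overwritten). 3-mer insertions do
#' not clear 9-mer provenance and vice versa; the distribution is estimated
#' over 9-mer usage by default.
#'
#' @param conf a `conformation`.
#' @param window a [fragment_window] valid for the conformation's length.
#' @param frag_index 1-based index into `window$fragments`.
#' @return the modified `conformation`.
#' @export
insert_fragment <- function(conf, window, frag_index) {
  len <- window$length
  start <- window$start
  n <- nrow(conf$torsions)
  if (start < 1L || start + len - 1L > n)
    stop("window [", start, ", ", start + len - 1L,
         "] out of range for ", n, " residues")
  if (frag_index < 1L || frag_index > length(window$fragments))
    stop("fragment index ", frag_index, " out of range")
  rows <- start:(start + len - 1L)
  conf$torsions[rows, ] <- window$fragments[[frag_index]]$torsions
  conf$coords <- build_coords(conf$torsions, conf$geometry)
  slot <- if (len == 9L) "provenance9" else "provenance3"
  conf[[slot]] <- .update_provenance(conf[[slot]], start, len, frag_index)
  conf
}

#' Optimal-superposition C-alpha RMSD
#'
#' Minimum root-mean-square deviation between corresponding alpha carbons
#' over all rigid-body superpositions (Kabsch algorithm, reflection-guarded
#' SVD). Symmetric and invariant under rotation/translation of either input.
#'
#' @param a,b `conformation`s, or m x 3 matrices of CA coordinates (use
#'   [ca_coords()] to extract CAs from a 3n x 3 backbone matrix first).
#' @return RMSD in Angstrom, >= 0.
#' @export
ca_rmsd <- function(a, b) {
  pa <- .as_ca(a)
  pb <- .as_ca(b)
  if (nrow(pa) != nrow(pb))
    stop("CA sets differ in size: ", nrow(pa), " vs ", nrow(pb))
  kabsch_rmsd_cpp(pa, pb)
}

.as_ca <- function(x) {
  if (inherits(x, "conformation")) return(ca_coords(x))
  as.matrix(x)
}

#' All-backbone-atom RMSD
#'
#' Same superposition as [ca_rmsd()] but over all N, CA, C atoms.
#'
#' @param a,b `conformation`s or 3n x 3 backbone matrices.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(a, b) {
  pa <- if (inherits(a, "conformation")) a$coords else as.matrix(a)
  pb <- if (inherits(b, "conformation")) b$coords else as.matrix(b)
  if (nrow(pa) != nrow(pb)) stop("backbones differ in size")
  kabsch_rmsd_cpp(pa, pb)
}

#' Write a backbone conformation as PDB
#'
#' Emits ATOM records for N, CA, C of each residue, chain A, 1-based resSeq,
#' occupancy 1.00. The B-factor column carries the 9-mer provenance window
#' start covering each residue (0.00 where no fragment is recorded), so
#' fragment usage survives a round trip through the file.
#'
#' @param conf a `conformation`.
#' @param path output PDB path.
#' @return invisibly, `path`.
#' @export
write_pdb_backbone <- function(conf, path) {
  n <- nchar(conf$sequence)
  aa3 <- bio3d::aa123(strsplit(conf$sequence, "")[[1]])
  bfac <- numeric(n)
  if (length(conf$provenance9)) {
    for (s in as.integer(names(conf$provenance9)))
      bfac[s:(s + 8L)] <- s
  }
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(conf$coords)),
                   resno = rep(seq_len(n), each = 3L),
                   resid = rep(aa3, each = 3L),
                   eleno = seq_len(3L * n),
                   elety = rep(c("N", "CA", "C"), n),
                   chain = rep("A", 3L * n),
                   o = rep(1, 3L * n),
                   b = rep(bfac, each = 3L))
  invisible(path)
}

#' Read a backbone (N, CA, C) model from a PDB file
#'
#' @param path PDB file with at least N, CA, C atoms per residue.
#' @return list with `sequence` and a 3n x 3 `coords` matrix.
#' @export
read_pdb_backbone <- function(path) {
  pdb <- bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, elety = c("N", "CA", "C"), verbose = FALSE)
  atoms <- pdb$atom[sel$atom, ]
  ord <- order(atoms$resno, match(atoms$elety, c("N", "CA", "C")))
  atoms <- atoms[ord, ]
  if (nrow(atoms) %% 3L != 0L)
    stop("incomplete backbone in ", path)
  ca <- atoms[atoms$elety == "CA", ]
  sequence <- paste(bio3d::aa321(ca$resid), collapse = "")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  list(sequence = sequence, coords = coords)
}
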