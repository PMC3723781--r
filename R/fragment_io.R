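#' Canonicalize torsion angles to (-180, 180]
#'
#' Wraps angles in degrees into the half-open interval (-180, 180], mapping
#' -180 to +180 so every torsion has a single representation (this is what
#' makes fragment-file round trips exact).
#'
#' @param x numeric vector or matrix of angles in degrees.
#' @return object of the same shape with all values in (-180, 180].
#' @export
canonicalize_torsion <- function(x) {
  r <- x %% 360
  shift <- which(r > 180)
  r[shift] <- r[shift] - 360
  r
}

#' Construct a backbone fragment
#'
#' A fragment is a short stretch of per-residue backbone torsions
#' (phi, psi, omega) excised from a known (or synthetic) structure, used as a
#' move unit during assembly. Torsions are canonicalized to (-180, 180].
#' Lengths other than 3 or 9 are accepted but flagged with a warning, since
#' standard libraries carry 9-mers and 3-mers.
#'
#' @param torsions numeric matrix with one row per residue and columns
#'   phi, psi, omega (degrees).
#' @param source_tag free-text provenance of the fragment, conventionally
#'   "<pdb> <chain> <resno>".
#' @return an object of class `fragment` with fields `torsions`,
#'   `source_tag` and `length`.
#' @export
fragment <- function(torsions, source_tag = "xxxx A 1") {
  torsions <- as.matrix(torsions)
  if (ncol(torsions) != 3L)
    stop("fragment torsions must have 3 columns (phi, psi, omega)")
  if (!is.numeric(torsions) || anyNA(torsions))
    stop("fragment torsions must be finite numbers")
  if (any(abs(torsions) > 180))
    stop("fragment torsions must lie in [-180, 180] degrees")
  torsions <- canonicalize_torsion(torsions)
  colnames(torsions) <- c("phi", "psi", "omega")
  len <- nrow(torsions)
  if (!len %in% c(3L, 9L))
    warning("fragment length ", len, " is non-standard (expected 3 or 9)")
  structure(list(torsions = torsions, source_tag = source_tag, length = len),
            class = "fragment")
}

#' Construct a fragment window
#'
#' A window is a contiguous target-sequence range starting at `start`
#' (1-based) holding the candidate fragments that can be inserted there. The
#' order of `fragments` is significant: it defines fragment index identity,
#' which the learned probability vectors are aligned to.
#'
#' @param start 1-based residue index of the first window position.
#' @param fragments list of [fragment] objects, all of the same length.
#' @return an object of class `fragment_window`.
#' @export
fragment_window <- function(start, fragments) {
  start <- as.integer(start)
  if (start < 1L) stop("window start must be >= 1")
  if (length(fragments) < 1L) stop("window needs at least one fragment")
  lens <- vapply(fragments, function(f) f$length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all fragments in a window must have the same length")
  structure(list(start = start, fragments = fragments,
                 length = lens[[1]]),
            class = "fragment_window")
}

#' Construct a fragment library
#'
#' @param target_length number of residues in the target sequence.
#' @param windows9 list of length-9 [fragment_window]s, sorted by start.
#' @param windows3 list of length-3 [fragment_window]s, sorted by start.
#' @return an object of class `fragment_library`.
#' @export
fragment_library <- function(target_length, windows9 = list(),
                             windows3 = list()) {
  target_length <- as.integer(target_length)
  check <- function(windows, len) {
    if (length(windows) == 0L) return(windows)
    starts <- vapply(windows, function(w) w$start, integer(1))
    if (is.unsorted(starts, strictly = TRUE))
      stop("windows must be sorted by strictly increasing start")
    wl <- vapply(windows, function(w) w$length, integer(1))
    if (any(wl != len)) stop("window of wrong fragment length in list")
    last <- max(starts + len - 1L)
    if (last > target_length)
      stop("window extends past target length (start ", max(starts), ")")
    windows
  }
  structure(list(target_length = target_length,
                 windows9 = check(windows9, 9L),
                 windows3 = check(windows3, 3L)),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  n9 <- length(x$windows9); n3 <- length(x$windows3)
  f9 <- if (n9) length(x$windows9[[1]]$fragments) else 0
  cat("Fragment library: target length", x$target_length, "residues\n",
      " ", n9, "nine-mer windows,", n3, "three-mer windows,",
      f9, "fragments per 9-mer window\n")
  cov <- library_coverage(x)
  cat("  9-mer coverage:", sprintf("%.0f%%", 100 * cov["cov9"]),
      " 3-mer coverage:", sprintf("%.0f%%", 100 * cov["cov3"]), "\n")
  invisible(x)
}

#' Fraction of possible window starts present in a library
#'
#' A dense library covers starts 1..L-8 with 9-mers and 1..L-2 with 3-mers.
#'
#' @param library a [fragment_library].
#' @return named numeric vector `c(cov9 = , cov3 = )`.
#' @export
library_coverage <- function(library) {
  L <- library$target_length
  frac <- function(windows, len) {
    want <- max(L - len + 1L, 0L)
    if (want == 0L) return(NA_real_)
    starts <- vapply(windows, function(w) w$start, integer(1))
    length(intersect(starts, seq_len(want))) / want
  }
  c(cov9 = frac(library$windows9, 9L), cov3 = frac(library$windows3, 3L))
}

.split_tag <- function(tag) {
  tok <- strsplit(trimws(tag), "\\s+")[[1]]
  if (length(tok) >= 3) tok[1:3] else c("xxxx", "A", "1")
}

#' Read a Rosetta-style fragment file
#'
#' Parses the minimal, documented subset of the Rosetta fragment-file layout:
#' a `position:` header per window, then fragments as blocks of per-residue
#' lines separated by blank lines. Each residue line carries at least eight
#' whitespace-separated fields:
#'
#' ```
#'  pdb chain resno aa ss     phi      psi    omega
#'  2jsv A       10  V  H -60.123  -45.000  180.000
#' ```
#'
#' Trailing columns beyond `omega` are ignored. Torsions must lie in
#' \[-180, 180\] degrees; -180 is canonicalized to +180 on load.
#'
#' @param path path to the fragment file.
#' @param frag_length expected fragment length, 3 or 9.
#' @return list of [fragment_window]s in file order.
#' @export
read_fragment_file <- function(path, frag_length) {
  if (!file.exists(path)) stop("no such fragment file: ", path)
  frag_length <- as.integer(frag_length)
  if (!frag_length %in% c(3L, 9L)) stop("frag_length must be 3 or 9")

  lines <- readLines(path)
  windows <- list()
  cur_start <- NA_integer_
  cur_frags <- list()
  cur_rows <- NULL
  cur_tag <- NULL

  flush_frag <- function() {
    if (is.null(cur_rows)) return()
    if (nrow(cur_rows) != frag_length)
      stop("fragment ending before line has ", nrow(cur_rows),
           " residues, expected ", frag_length,
           " (window start ", cur_start, ")")
    cur_frags[[length(cur_frags) + 1L]] <<-
      fragment(cur_rows, source_tag = cur_tag)
    cur_rows <<- NULL
    cur_tag <<- NULL
  }
  flush_window <- function() {
    flush_frag()
    if (!is.na(cur_start)) {
      if (length(cur_frags) == 0L)
        stop("position block at start ", cur_start, " has no fragments")
      windows[[length(windows) + 1L]] <<-
        fragment_window(cur_start, cur_frags)
    }
    cur_frags <<- list()
  }

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (grepl("^\\s*position:", line)) {
      flush_window()
      m <- regmatches(line, regexec("position:\\s*(\\d+)", line))[[1]]
      if (length(m) < 2)
        stop("malformed position header at line ", ln)
      cur_start <- as.integer(m[2])
      next
    }
    if (!nzchar(trimws(line))) {
      flush_frag()
      next
    }
    if (is.na(cur_start))
      stop("fragment data before any position header at line ", ln)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) < 8)
      stop("malformed fragment line ", ln, ": expected >= 8 fields, got ",
           length(tok))
    tors <- suppressWarnings(as.numeric(tok[6:8]))
    if (anyNA(tors))
      stop("malformed fragment line ", ln, ": non-numeric torsion")
    if (any(abs(tors) > 180))
      stop("torsion out of range at line ", ln, " (window start ", cur_start,
           ", fragment ", length(cur_frags) + 1L, "): ",
           paste(tors, collapse = " "))
    if (is.null(cur_rows)) cur_tag <- paste(tok[1:3], collapse = " ")
    cur_rows <- rbind(cur_rows, tors)
  }
  flush_window()
  windows
}

#' Write fragment windows in Rosetta-style layout
#'
#' Inverse of [read_fragment_file()]: `read_fragment_file(write_fragment_file(w))`
#' reproduces `w` field by field (torsions serialized to 3 decimals and
#' canonicalized to (-180, 180]).
#'
#' @param windows list of [fragment_window]s.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_fragment_file <- function(windows, path) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  for (w in windows) {
    writeLines(sprintf("position: %12d neighbors: %10d",
                       w$start, length(w$fragments)), con)
    writeLines("", con)
    for (f in w$fragments) {
      tag <- .split_tag(f$source_tag)
      tor <- canonicalize_torsion(f$torsions)
      for (i in seq_len(nrow(tor))) {
        writeLines(sprintf(" %4s %s %5s A L %9.3f %9.3f %9.3f",
                           tag[1], tag[2], tag[3],
                           tor[i, 1], tor[i, 2], tor[i, 3]), con)
      }
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Read a single-record FASTA target sequence
#'
#' @param path FASTA file with exactly one record of standard one-letter
#'   amino-acid codes; at least 9 residues (one 9-mer window).
#' @return uppercase amino-acid string.
#' @export
read_sequence <- function(path) {
  fa <- bio3d::read.fasta(path)
  if (nrow(fa$ali) != 1L)
    stop("expected a single-record FASTA, found ", nrow(fa$ali), " records")
  seq <- toupper(paste(fa$ali[1, fa$ali[1, ] != "-"], collapse = ""))
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), letters20)
  if (length(bad))
    stop("non-standard amino-acid letters in sequence: ",
         paste(bad, collapse = ", "))
  if (nchar(seq) < 9L)
    stop("sequence has ", nchar(seq), " residues; need at least 9")
  seq
}

#' Write a target sequence as FASTA
#'
#' @param sequence amino-acid string.
#' @param path output path.
#' @param id record identifier.
#' @return invisibly, `path`.
#' @export
write_sequence <- function(sequence, path, id = "target") {
  writeLines(c(paste0(">", id), sequence), path)
  invisible(path)
}
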