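#' Residue classes of the HNP alphabet
#'
#' Beads come in three flavours: hydrophobic (H), neutral (N) and
#' hydrophilic (P).  Only H-H nonbonded pairs attract; all other pairs are
#' purely repulsive (see [forcefield()]).
#'
#' @format character vector of the three one-letter class labels.
#' @export
residue_classes <- c("H", "N", "P")

# Grouping of the 20 standard amino acids into the three classes.
.aa_class <- c(
  PHE = "H", MET = "H", ILE = "H", LEU = "H", TRP = "H", VAL = "H",
  CYS = "H", TYR = "H",
  HIS = "N", ALA = "N", GLY = "N", THR = "N",
  LYS = "P", ASP = "P", ASN = "P", GLU = "P", GLN = "P", SER = "P",
  PRO = "P", ARG = "P")

.aa_one_to_three <- c(
  F = "PHE", M = "MET", I = "ILE", L = "LEU", W = "TRP", V = "VAL",
  C = "CYS", Y = "TYR", H = "HIS", A = "ALA", G = "GLY", T = "THR",
  K = "LYS", D = "ASP", N = "ASN", E = "GLU", Q = "GLN", S = "SER",
  P = "PRO", R = "ARG")

#' Parse a repeat-unit specification string
#'
#' A repeat unit is written as a concatenation of `<class letter><count>`
#' pairs over the alphabet H/N/P, e.g. `"H3N1P1"` = three hydrophobic, one
#' neutral, one hydrophilic bead.
#'
#' @param spec character scalar such as `"H3N1P1"`.
#' @return an object of class `hnp_unit`: list with `blocks` (data.frame of
#'   `class`, `count`), `name` (normalized spelling) and `length` (total
#'   beads per unit).
#' @examples
#' parse_repeat_spec("H3N1P1")
#' @export
parse_repeat_spec <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(spec))
    stop("repeat-unit spec must be a single non-empty string")
  tokens <- regmatches(spec, gregexpr("[A-Za-z]+[0-9]*|[0-9]+", spec))[[1]]
  if (paste(tokens, collapse = "") != spec)
    stop("cannot tokenize repeat-unit spec: ", sQuote(spec))
  cls <- character(0); cnt <- integer(0)
  for (tok in tokens) {
    m <- regmatches(tok, regexec("^([A-Za-z])([0-9]+)$", tok))[[1]]
    if (length(m) != 3L)
      stop("malformed token ", sQuote(tok), " in repeat-unit spec ",
           sQuote(spec), " (expected <letter><count>)")
    letter <- toupper(m[2]); count <- as.integer(m[3])
    if (!letter %in% residue_classes)
      stop("unknown residue class ", sQuote(m[2]), " in ", sQuote(spec),
           " (alphabet is H, N, P)")
    if (is.na(count) || count < 1L)
      stop("count for class ", letter, " must be a positive integer, got ",
           sQuote(m[3]))
    cls <- c(cls, letter); cnt <- c(cnt, count)
  }
  unit <- list(
    blocks = data.frame(class = cls, count = cnt, stringsAsFactors = FALSE),
    name = paste0(cls, cnt, collapse = ""),
    length = sum(cnt))
  class(unit) <- "hnp_unit"
  unit
}

#' @export
print.hnp_unit <- function(x, ...) {
  cat("<hnp_unit> ", x$name, " (", x$length, " beads/unit)\n", sep = "")
  invisible(x)
}

#' Build a residue-class sequence by tiling a repeat unit
#'
#' The unit is repeated in block order and truncated at `n` beads.  All
#' chain lengths used in the reference study (N = 50, 120, 240, 300) are
#' multiples of their unit lengths, so truncation never splits a unit there.
#'
#' @param unit an `hnp_unit` from [parse_repeat_spec()], or a spec string.
#' @param n total number of beads (>= 5; the first dihedral needs 4 beads).
#' @return an object of class `hnp_sequence`: character vector of class
#'   labels with attributes `unit` (provenance) and `name`.
#' @examples
#' build_sequence("H3N1P1", 10)
#' @export
build_sequence <- function(unit, n) {
  if (is.character(unit)) unit <- parse_repeat_spec(unit)
  stopifnot(inherits(unit, "hnp_unit"))
  n <- as.integer(n)
  if (is.na(n) || n < 5L)
    stop("chain length must be at least 5 beads, got ", n)
  tile <- rep(unit$blocks$class, times = unit$blocks$count)
  classes <- rep_len(tile, n)
  structure(classes, unit = unit$name, class = "hnp_sequence")
}

#' Construct a sequence from explicit class labels
#'
#' @param classes character vector over {"H","N","P"}.
#' @return an `hnp_sequence` with provenance `"explicit"`.
#' @export
as_hnp_sequence <- function(classes) {
  if (inherits(classes, "hnp_sequence")) return(classes)
  classes <- toupper(as.character(classes))
  bad <- setdiff(unique(classes), residue_classes)
  if (length(bad))
    stop("invalid residue class label(s): ", paste(bad, collapse = ", "))
  if (length(classes) < 5L)
    stop("chain length must be at least 5 beads")
  structure(classes, unit = "explicit", class = "hnp_sequence")
}

#' @export
print.hnp_sequence <- function(x, ...) {
  cat("<hnp_sequence> N=", length(x), " unit=", attr(x, "unit"), "\n", sep = "")
  cat(" ", paste(unclass(x)[seq_len(min(60, length(x)))], collapse = ""),
      if (length(x) > 60) "...", "\n", sep = "")
  invisible(x)
}

# integer encoding used by the C++ core: H=0, N=1, P=2
.class_index <- function(seq) match(unclass(seq), residue_classes) - 1L

#' Classify a standard amino acid into the HNP alphabet
#'
#' Hydrophobic (H): Phe, Met, Ile, Leu, Trp, Val, Cys, Tyr.  Neutral (N):
#' His, Ala, Gly, Thr.  Hydrophilic (P): Lys, Asp, Asn, Glu, Gln, Ser, Pro,
#' Arg.
#'
#' @param residue one- or three-letter amino-acid code(s), case-insensitive.
#' @return character vector of class labels ("H", "N" or "P").
#' @examples
#' classify_amino_acid(c("Phe", "His", "Lys"))
#' classify_amino_acid("FMHK")  # also accepts a one-letter string
#' @export
classify_amino_acid <- function(residue) {
  residue <- as.character(residue)
  if (length(residue) == 1L && nchar(residue) > 3L &&
      all(strsplit(toupper(residue), "")[[1]] %in% names(.aa_one_to_three)))
    residue <- strsplit(residue, "")[[1]]
  up <- toupper(residue)
  three <- ifelse(nchar(up) == 1L, .aa_one_to_three[up], up)
  out <- .aa_class[three]
  if (anyNA(out))
    stop("not a standard amino-acid code: ",
         paste(sQuote(residue[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Generate a seeded initial chain configuration
#'
#' Builds a self-avoiding random walk with every bond at the equilibrium
#' length `l0`: bond angles are drawn uniformly in a window around the
#' equilibrium angle and dihedrals uniformly in (-pi, pi], rejecting
#' placements that bring any nonbonded pair (|i-j| >= 4) closer than
#' `0.8 * sigma`.  Velocities are Maxwell-Boltzmann at the requested
#' temperature with net linear and angular momentum projected out.
#'
#' @param seq an `hnp_sequence` (or repeat-unit spec plus `n`).
#' @param seed integer seed; identical seed gives a bit-identical state.
#' @param Tstar reduced temperature for the initial velocities (default 1.5,
#'   a high-temperature coil start).
#' @param ff force field supplying `l0`, `theta0`, `sigma`.
#' @param mass per-bead mass in g/mol (default 110, the mean residue mass).
#' @param max_retries placement attempts per bead before restarting the walk.
#' @param max_restarts whole-walk restarts before giving up.
#' @return an object of class `hnp_state`: list with `positions` (N x 3 nm),
#'   `velocities` (N x 3 nm/ps), `masses`, `sequence`, `time` (ps).
#' @export
initial_configuration <- function(seq, seed, Tstar = 1.5, ff = forcefield(),
                                  mass = 110, max_retries = 200L,
                                  max_restarts = 50L) {
  seq <- as_hnp_sequence(seq)
  n <- length(seq)
  set.seed(as.integer(seed))
  l0 <- ff$l0; th0 <- ff$theta0; rmin <- 0.8 * ff$sigma

  place_walk <- function() {
    pos <- matrix(NA_real_, n, 3)
    pos[1, ] <- c(0, 0, 0)
    pos[2, ] <- c(l0, 0, 0)
    # third bead fixes the first bond deflection angle
    th <- runif(1, th0 - 0.35, th0 + 0.35)
    pos[3, ] <- pos[2, ] + l0 * c(cos(th), sin(th), 0)
    for (i in 4:n) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        th <- runif(1, th0 - 0.35, th0 + 0.35)
        phi <- runif(1, -pi, pi)
        # local frame at bead i-1
        b2 <- pos[i - 1, ] - pos[i - 2, ]
        b1 <- pos[i - 2, ] - pos[i - 3, ]
        e1 <- b2 / sqrt(sum(b2^2))
        nv <- c(b1[2] * b2[3] - b1[3] * b2[2],
                b1[3] * b2[1] - b1[1] * b2[3],
                b1[1] * b2[2] - b1[2] * b2[1])
        nn <- sqrt(sum(nv^2))
        if (nn < 1e-12) nv <- c(0, 0, 1) else nv <- nv / nn
        e2 <- c(nv[2] * e1[3] - nv[3] * e1[2],
                nv[3] * e1[1] - nv[1] * e1[3],
                nv[1] * e1[2] - nv[2] * e1[1])
        cand <- pos[i - 1, ] + l0 * (cos(th) * e1 +
                 sin(th) * (cos(phi) * e2 + sin(phi) * nv))
        js <- seq_len(i - 4)   # nonbonded partners of bead i: |i-j| >= 4
        ok <- TRUE
        if (length(js)) {
          d2 <- rowSums((pos[js, , drop = FALSE] -
                         matrix(cand, length(js), 3, byrow = TRUE))^2)
          ok <- all(d2 > rmin^2)
        }
        if (ok) { pos[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) return(NULL)
    }
    pos
  }

  pos <- NULL
  for (restart in seq_len(max_restarts)) {
    pos <- place_walk()
    if (!is.null(pos)) break
  }
  if (is.null(pos))
    stop("self-avoiding walk failed after ", max_restarts,
         " restarts; try a different seed")

  masses <- rep(mass, n)
  Tk <- tstar_to_kelvin(Tstar, ff)
  # Maxwell-Boltzmann: component sd = sqrt(kB T / m) in nm/ps
  sdv <- sqrt(.kB * .kcal * Tk / masses)
  vel <- matrix(rnorm(3 * n), n, 3) * sdv
  st <- structure(
    list(positions = pos, velocities = vel, masses = masses,
         sequence = seq, time = 0),
    class = "hnp_state")
  remove_rigid_motion(st)
}

#' @export
print.hnp_state <- function(x, ...) {
  cat("<hnp_state> N=", nrow(x$positions), " t=", signif(x$time, 4), " ps\n",
      sep = "")
  invisible(x)
}

.validate_state <- function(state) {
  stopifnot(inherits(state, "hnp_state"))
  n <- nrow(state$positions)
  if (!all(is.finite(state$positions))) stop("non-finite positions")
  if (n != length(state$sequence))
    stop("positions (", n, ") and sequence (", length(state$sequence),
         ") lengths differ")
  if (any(state$masses <= 0)) stop("masses must be positive")
  invisible(state)
}

#' Read and write HNP sequences as FASTA
#'
#' Sequences are stored as single-record FASTA over the alphabet {H,N,P}.
#' Files containing standard amino-acid letters are converted through
#' [classify_amino_acid()].
#'
#' @param path file path.
#' @param seq an `hnp_sequence`.
#' @param name FASTA record name.
#' @return `read_sequence_fasta` returns an `hnp_sequence`;
#'   `write_sequence_fasta` returns `path` invisibly.
#' @export
write_sequence_fasta <- function(seq, path, name = attr(seq, "unit")) {
  seq <- as_hnp_sequence(seq)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::BStringSet(paste(unclass(seq), collapse = ""))
    names(x) <- name
    Biostrings::writeXStringSet(x, path)
  } else {
    writeLines(c(paste0(">", name), paste(unclass(seq), collapse = "")), path)
  }
  invisible(path)
}

#' @rdname write_sequence_fasta
#' @export
read_sequence_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readBStringSet(path)
    if (length(x) != 1L) stop("expected a single FASTA record, found ", length(x))
    letters <- strsplit(as.character(x[[1]]), "")[[1]]
  } else {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, ">")]
    letters <- strsplit(paste(body, collapse = ""), "")[[1]]
  }
  letters <- toupper(letters)
  if (!all(letters %in% residue_classes))
    letters <- classify_amino_acid(letters)
  as_hnp_sequence(letters)
}
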