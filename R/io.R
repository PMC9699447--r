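#' Write a trajectory as multi-frame XYZ
#'
#' Standard XYZ blocks: bead count, a comment line carrying the frame's
#' step, time and target temperature, then one `<class letter> x y z` row
#' per bead (coordinates in nm).
#'
#' @param traj an `hnp_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "hnp_trajectory"))
  n <- dim(traj$frames)[2]
  cls <- unclass(traj$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(dim(traj$frames)[1])) {
    fi <- traj$frame_info[i, ]
    writeLines(c(
      as.character(n),
      sprintf("step=%d time_ps=%.6f Tstar=%.6g leg=%d",
              fi$step, fi$time_ps, fi$Tstar_target, fi$leg),
      sprintf("%s %.9f %.9f %.9f", cls,
              traj$frames[i, , 1], traj$frames[i, , 2], traj$frames[i, , 3])),
      con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Inverse of [write_xyz()].  Frame metadata is recovered from the comment
#' lines when present.
#'
#' @param path XYZ file path.
#' @return list with `frames` (n_frames x N x 3 array), `sequence`
#'   (`hnp_sequence`, when the element column uses the H/N/P alphabet) and
#'   `frame_info` (data.frame).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); info <- list(); k <- 1; i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1]
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    cls <- vapply(parts, `[[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[k]] <- xyz
    g <- function(key) {
      m <- regmatches(comment, regexec(paste0(key, "=([-0-9.eE+]+)"), comment))[[1]]
      if (length(m) == 2) as.numeric(m[2]) else NA_real_
    }
    info[[k]] <- data.frame(step = g("step"), time_ps = g("time_ps"),
                            Tstar_target = g("Tstar"), leg = g("leg"))
    k <- k + 1; i <- i + 2 + n
  }
  arr <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (j in seq_along(frames)) arr[j, , ] <- frames[[j]]
  seq <- if (all(cls %in% residue_classes)) as_hnp_sequence(cls) else NULL
  list(frames = arr, sequence = seq, frame_info = do.call(rbind, info))
}

#' Write one frame as a CA-only PDB
#'
#' Each bead becomes a `CA` ATOM record; the residue name encodes the HNP
#' class (HPH, NEU, PHI).  Coordinates are converted from nm to Angstrom.
#'
#' @param state an `hnp_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(state, path) {
  .validate_state(state)
  resname <- c(H = "HPH", N = "NEU", P = "PHI")[unclass(state$sequence)]
  pos <- state$positions * 10   # nm -> Angstrom
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(pos)), resname, seq_len(nrow(pos)),
    pos[, 1], pos[, 2], pos[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write or read a run's metadata sidecar (JSON)
#'
#' Records the protocol (schedule, dt, tau, seed, strides), the force-field
#' parameters and the sequence, so a trajectory file can be re-analyzed
#' without the originating R session.
#'
#' @param traj an `hnp_trajectory`.
#' @param path sidecar path (conventionally `<run>.json`).
#' @return `write_run_metadata` returns `path` invisibly;
#'   `read_run_metadata` returns a list with `protocol`, `ff`, `sequence`.
#' @export
write_run_metadata <- function(traj, path) {
  stopifnot(inherits(traj, "hnp_trajectory"))
  meta <- list(
    protocol = unclass(traj$protocol),
    forcefield = unclass(traj$ff),
    sequence = paste(unclass(traj$sequence), collapse = ""),
    unit = attr(traj$sequence, "unit"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_metadata
#' @export
read_run_metadata <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- x$protocol
  list(
    protocol = run_protocol(as.data.frame(p$schedule), dt = p$dt, tau = p$tau,
                            seed = p$seed, snapshot_stride = p$snapshot_stride,
                            sample_stride = p$sample_stride),
    ff = forcefield(
      l0 = x$forcefield$l0, kd = x$forcefield$kd, theta0 = x$forcefield$theta0,
      ktheta = x$forcefield$ktheta, kphi = x$forcefield$kphi,
      sigma = x$forcefield$sigma, eps_h = x$forcefield$eps_h,
      Rc = x$forcefield$Rc,
      epsilon_matrix = matrix(unlist(x$forcefield$epsilon_matrix), 3, 3),
      lambda_matrix = matrix(unlist(x$forcefield$lambda_matrix), 3, 3),
      shift_at_cutoff = isTRUE(x$forcefield$shift_at_cutoff)),
    sequence = as_hnp_sequence(strsplit(x$sequence, "")[[1]]))
}
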