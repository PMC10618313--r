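CHAIN_CHARS <- c(LETTERS, letters, 0:9)

#' Write a simulation frame
#'
#' PDB (one CA-style atom per residue, chain identifiers, CRYST1 box
#' record) or XYZ with a box sidecar file.  Coordinates are in Angstrom;
#' on writing, Z is shifted so the lower wall sits at 0.  Chain IDs use
#' A-Z, a-z, 0-9 and cycle beyond 62 chains (readers recover chains from
#' the per-chain residue numbering, which restarts at 1).
#'
#' @param state a `dsb_state` or an N x 3 matrix with `box`.
#' @param path output file.
#' @param topology the matching [dsb_topology()].
#' @param format "pdb" or "xyz".
#' @param box a [dsb_box()] when `state` is a bare matrix.
#' @return the path, invisibly.
#' @export
write_frame <- function(state, path, topology, format = c("pdb", "xyz"),
                        box = NULL) {
  format <- match.arg(format)
  if (inherits(state, "dsb_state")) {
    x <- state$x
    box <- state$box
  } else x <- as.matrix(state)
  if (!nrow(x)) stop("refusing to write an empty system")
  if (nrow(x) != topology$n_residues)
    stop("coordinates do not match the topology")
  x[, 3] <- x[, 3] - box$zlo
  if (format == "xyz") {
    hdr <- sprintf("box %.6f %.6f %.6f %.6f %.6f", box$Lx, box$Ly,
                   box$tilt, 0, box$zhi - box$zlo)
    lines <- c(sprintf("%d", nrow(x)), hdr,
               sprintf("%s %12.6f %12.6f %12.6f %d",
                       topology$sequence, x[, 1], x[, 2], x[, 3],
                       topology$chain_id))
    writeLines(lines, path)
    return(invisible(path))
  }
  blen <- sqrt(box$tilt^2 + box$Ly^2)
  gamma <- acos(box$tilt / blen) * 180 / pi
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   box$Lx, blen, box$zhi - box$zlo, 90, 90, gamma)
  res3 <- bio3d::aa123(topology$sequence)
  within <- sequence(topology$chain_lengths)
  cid <- CHAIN_CHARS[(topology$chain_id - 1L) %% 62L + 1L]
  atoms <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    (seq_len(nrow(x)) - 1L) %% 99999L + 1L, res3, cid,
    (within - 1L) %% 9999L + 1L, x[, 1], x[, 2], x[, 3], 1, 0)
  writeLines(c(cryst, atoms, "END"), path)
  invisible(path)
}

#' Read a simulation frame
#'
#' Reads PDB (via bio3d; box from the CRYST1 record, chains from the
#' chain IDs and residue-number restarts) or the XYZ-with-box-sidecar
#' dialect written by [write_frame()].
#'
#' @param path input file.
#' @param format inferred from the extension when missing.
#' @return list with `x` (N x 3), `box`, and the reconstructed
#'   `topology`.
#' @export
read_frame <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz"
              else "pdb"
  if (format == "xyz") {
    lines <- readLines(path)
    n <- as.integer(lines[1])
    hdr <- as.numeric(strsplit(lines[2], "\\s+")[[1]][-1])
    d <- read.table(text = lines[3:(2 + n)],
                    col.names = c("el", "x", "y", "z", "chain"))
    box <- dsb_box(hdr[1], hdr[2], hdr[4], hdr[5], tilt = hdr[3])
    seqs <- tapply(d$el, d$chain, paste, collapse = "")
    top <- dsb_topology(as.character(seqs[order(as.integer(names(seqs)))]))
    return(list(x = cbind(d$x, d$y, d$z), box = box, topology = top))
  }
  pdb <- bio3d::read.pdb(path)
  ca <- pdb$atom
  lines <- readLines(path, n = 50)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) stop("PDB file has no CRYST1 box record")
  a <- as.numeric(substr(cl[1], 7, 15))
  blen <- as.numeric(substr(cl[1], 16, 24))
  cc <- as.numeric(substr(cl[1], 25, 33))
  gamma <- as.numeric(substr(cl[1], 48, 54)) * pi / 180
  tilt <- blen * cos(gamma)
  if (abs(tilt) < 1e-6) tilt <- 0
  Ly <- blen * sin(gamma)
  box <- dsb_box(a, Ly, 0, cc, tilt = tilt)
  # chain boundaries: chain-ID change or residue numbering restart
  newc <- c(TRUE, diff(ca$resno) < 1 |
              ca$chain[-1] != ca$chain[-nrow(ca)])
  chain <- cumsum(newc)
  seq1 <- bio3d::aa321(ca$resid)
  seqs <- tapply(seq1, chain, paste, collapse = "")
  top <- dsb_topology(as.character(seqs))
  list(x = cbind(ca$x, ca$y, ca$z), box = box, topology = top)
}

#' Read a run-configuration file
#'
#' YAML with sections mirroring the module surfaces: `sequences` (strings
#' or a `fasta` path), `params` (overrides for [dsb_params()]),
#' `schedule` (arguments of [dsb_schedule()]), `rho_list`, `repeats`,
#' `seed`, `out`.
#'
#' @param path YAML file.
#' @return named list of configuration sections.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  yaml::read_yaml(path)
}

config_topology <- function(cfg, dir = ".") {
  if (!is.null(cfg$fasta)) {
    p <- cfg$fasta
    if (!file.exists(p)) p <- file.path(dir, cfg$fasta)
    read_sequences(p)
  } else if (!is.null(cfg$sequences)) {
    dsb_topology(unlist(cfg$sequences))
  } else stop("config needs 'sequences' or 'fasta'")
}

write_observable_csv <- function(df, path, units) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

provenance_record <- function(config_path = NULL, seed = NULL) {
  c(sprintf("package: dsbsim %s",
            as.character(utils::packageVersion("dsbsim"))),
    if (!is.null(config_path))
      sprintf("config_md5: %s", unname(tools::md5sum(config_path))),
    if (!is.null(seed)) sprintf("seed: %d", as.integer(seed)),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
}
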