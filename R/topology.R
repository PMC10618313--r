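#' System topology: chains, residue types, disulfide-capable sites
#'
#' A topology lists every residue of the multichain system in chain order,
#' with its amino-acid type, chain membership, cysteine flag, and any
#' always-attractive structure-based (Go) contacts.  Bonded pairs, angle
#' triples and dihedral quads follow from chain contiguity.
#'
#' @param sequences character vector of one-letter amino-acid sequences,
#'   one element per chain (repeat an element for multiple copies).
#' @param go_contacts optional data frame with columns `i`, `j` (global
#'   1-based residue indices within the same chain) and `r0` (target
#'   distance in Angstrom).
#' @return An object of class `dsb_topology`.
#' @examples
#' top <- dsb_topology(c("GQQPGQ", "GQQPGQ"))
#' top$n_chains
#' @export
dsb_topology <- function(sequences, go_contacts = NULL) {
  sequences <- as.character(sequences)
  if (!length(sequences)) stop("need at least one chain")
  res <- strsplit(toupper(sequences), "")
  bad <- setdiff(unique(unlist(res)), AA_CODES)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  lens <- lengths(res)
  if (any(lens < 1)) stop("empty chain")
  letters1 <- unlist(res)
  type_code <- match(letters1, AA_CODES)
  chain_id <- rep(seq_along(res), lens)
  t <- list(
    n_residues = length(letters1),
    n_chains = length(res),
    sequence = letters1,
    type_code = as.integer(type_code),
    chain_id = as.integer(chain_id),
    is_cysteine = letters1 == "C",
    chain_lengths = as.integer(lens))
  if (!is.null(go_contacts) && nrow(go_contacts)) {
    go <- data.frame(i = as.integer(go_contacts$i),
                     j = as.integer(go_contacts$j),
                     r0 = as.numeric(go_contacts$r0))
    if (any(go$i < 1 | go$j < 1 | go$i > t$n_residues | go$j > t$n_residues))
      stop("go contact indices out of range")
    if (any(t$chain_id[go$i] != t$chain_id[go$j]))
      stop("go contacts must be intra-chain")
    if (any(abs(go$i - go$j) <= 2))
      stop("go contacts must separate residues by at least 3 along the chain")
    if (any(go$r0 <= 0)) stop("go distances must be positive")
    sw <- go$i > go$j
    tmp <- go$i[sw]; go$i[sw] <- go$j[sw]; go$j[sw] <- tmp
    go <- go[!duplicated(go[c("i", "j")]), , drop = FALSE]
    t$go_contacts <- go
  } else {
    t$go_contacts <- data.frame(i = integer(), j = integer(), r0 = numeric())
  }
  class(t) <- "dsb_topology"
  t
}

#' @export
print.dsb_topology <- function(x, ...) {
  cat(sprintf("DSB topology: %d residues in %d chain(s)\n",
              x$n_residues, x$n_chains))
  cat(sprintf("  chain lengths: %s\n",
              paste(x$chain_lengths, collapse = ", ")))
  cat(sprintf("  cysteines: %d, go contacts: %d\n",
              sum(x$is_cysteine), nrow(x$go_contacts)))
  invisible(x)
}

#' Residue index ranges of each chain
#' @param topology a [dsb_topology()].
#' @return data frame with columns `chain`, `from`, `to` (global 1-based).
#' @export
chain_ranges <- function(topology) {
  to <- cumsum(topology$chain_lengths)
  data.frame(chain = seq_along(to),
             from = c(1L, head(to, -1) + 1L), to = to)
}

#' Bonded residue pairs implied by chain connectivity
#' @param topology a [dsb_topology()].
#' @return two-column integer matrix of (i, i+1) pairs, one per bond.
#' @export
bonded_pairs <- function(topology) {
  cr <- chain_ranges(topology)
  do.call(rbind, lapply(seq_len(nrow(cr)), function(c) {
    if (cr$to[c] == cr$from[c]) return(NULL)
    i <- cr$from[c]:(cr$to[c] - 1L)
    cbind(i = i, j = i + 1L)
  }))
}

#' Read chain sequences from a FASTA file
#'
#' Each FASTA record is one chain; a `copies=K` token in the description
#' line replicates the chain K times.  Cysteines are flagged from the
#' sequence.
#'
#' @param path FASTA file path.
#' @return A [dsb_topology()].
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("empty FASTA file: ", path)
  out <- character(0)
  for (k in seq_along(seqs)) {
    header <- names(seqs)[k]
    copies <- 1L
    m <- regmatches(header, regexpr("copies=[^[:space:]]+", header))
    if (length(m) && nzchar(m)) {
      val <- sub("copies=", "", m)
      copies <- suppressWarnings(as.integer(val))
      if (is.na(copies) || copies < 1)
        stop("malformed copies= token in FASTA header: ", header)
    }
    out <- c(out, rep(as.character(seqs[[k]]), copies))
  }
  dsb_topology(out)
}

#' Read a structure-based (Go) contact map
#'
#' Whitespace-separated columns `chain_id i j distance`, residue indices
#' 1-based within the chain.  Contacts are intra-chain and applied to every
#' copy of nothing -- the chain ids refer to the chains of `topology`.
#'
#' @param path text file path.
#' @param topology the [dsb_topology()] the map refers to.
#' @return data frame with global indices `i`, `j` and `r0`, suitable for
#'   [dsb_topology()]'s `go_contacts`.
#' @export
read_contact_map <- function(path, topology) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.table(path, header = FALSE,
                  col.names = c("chain", "i", "j", "r0"))
  cr <- chain_ranges(topology)
  if (any(d$chain < 1 | d$chain > nrow(cr)))
    stop("contact map chain id out of range")
  off <- cr$from[d$chain] - 1L
  len <- topology$chain_lengths[d$chain]
  if (any(d$i < 1 | d$j < 1 | d$i > len | d$j > len))
    stop("contact map residue index out of range for its chain")
  data.frame(i = d$i + off, j = d$j + off, r0 = d$r0)
}
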