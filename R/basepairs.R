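#' Detect Watson-Crick base pairs in a DNA duplex
#'
#' Pairing is purely geometric and hydrogen-free: a purine and a pyrimidine
#' on opposite strands pair when their purine-N1 to pyrimidine-N3 distance
#' is at most 3.5 A and the C1'-C1' distance lies within 10.4 +/- 1.5 A.
#' Ambiguous candidates are resolved by minimal N1-N3 distance, ties by
#' lower residue number. Local antiparallelity is enforced through the
#' partner ordering: walking strand 1 in increasing residue number, partner
#' residue numbers must strictly decrease (the robust, twist-insensitive
#' form of the local direction criterion).
#'
#' Residues are classified by a residue-name whitelist (DA/DG/DC/DT and
#' one-letter variants); any other residue bearing a C1' atom in the DNA
#' chains raises a pairing failure rather than being silently skipped.
#'
#' @param structure a `gyre_structure`.
#' @param dna_chains character vector of the two strand chain ids
#'   (strand 1 first), or `"auto"` to use the two chains containing
#'   nucleotide residues.
#' @return data frame of pairs ordered along strand 1 (5'->3' taken as
#'   increasing author residue number) with columns `chain1`, `resnum1`,
#'   `resname1`, `chain2`, `resnum2`, `resname2`, `purine_side`; the source
#'   structure is attached as attribute `structure`.
#' @export
detect_base_pairs <- function(structure, dna_chains = "auto") {
  at <- structure$atoms
  nuc <- at[at$resid %in% c(PURINES, PYRIMIDINES) & at$elety == "C1'", ,
            drop = FALSE]
  if (identical(dna_chains, "auto")) {
    dna_chains <- sort(unique(nuc$chain))
    if (length(dna_chains) != 2L)
      gd_abort("gyredyn_pairing_failure", sprintf(
        "auto-detection found %d nucleotide chain(s); need exactly 2",
        length(dna_chains)))
  }
  if (length(dna_chains) != 2L)
    gd_abort("gyredyn_pairing_failure", "dna_chains must name two chains")

  # whitelist check: any C1'-bearing residue in these chains must be a
  # recognized nucleotide
  cand <- at[at$chain %in% dna_chains & at$elety == "C1'", , drop = FALSE]
  bad <- !(cand$resid %in% c(PURINES, PYRIMIDINES))
  if (any(bad))
    gd_abort("gyredyn_pairing_failure", paste(
      "unrecognized nucleotide residue(s):",
      paste(unique(paste0(cand$chain[bad], ":", cand$resno[bad], " ",
                          cand$resid[bad])), collapse = ", ")))

  res_table <- function(ch) {
    r <- cand[cand$chain == ch, , drop = FALSE]
    if (!nrow(r))
      gd_abort("gyredyn_pairing_failure",
               sprintf("chain %s contains no nucleotides", ch))
    r <- r[order(r$resno), , drop = FALSE]
    r$purine <- r$resid %in% PURINES
    base_atom <- ifelse(r$purine, "N1", "N3")
    key_all <- paste(at$chain, at$resno, at$elety, sep = "\r")
    brow <- match(paste(ch, r$resno, base_atom, sep = "\r"), key_all)
    r$bx <- at$x[brow]; r$by <- at$y[brow]; r$bz <- at$z[brow]
    r
  }
  s1 <- res_table(dna_chains[1L])
  s2 <- res_table(dna_chains[2L])

  # candidate purine-pyrimidine pairs across the strands
  cand_pairs <- rbind(
    expand.grid(i = which(s1$purine & !is.na(s1$bx)),
                j = which(!s2$purine & !is.na(s2$bx))),
    expand.grid(i = which(!s1$purine & !is.na(s1$bx)),
                j = which(s2$purine & !is.na(s2$bx))))
  if (!nrow(cand_pairs))
    gd_abort("gyredyn_pairing_failure", "no purine/pyrimidine candidates")
  d_base <- sqrt((s1$bx[cand_pairs$i] - s2$bx[cand_pairs$j])^2 +
                 (s1$by[cand_pairs$i] - s2$by[cand_pairs$j])^2 +
                 (s1$bz[cand_pairs$i] - s2$bz[cand_pairs$j])^2)
  d_c1 <- sqrt((s1$x[cand_pairs$i] - s2$x[cand_pairs$j])^2 +
               (s1$y[cand_pairs$i] - s2$y[cand_pairs$j])^2 +
               (s1$z[cand_pairs$i] - s2$z[cand_pairs$j])^2)
  ok <- d_base <= 3.5 & d_c1 >= 10.4 - 1.5 & d_c1 <= 10.4 + 1.5
  cand_pairs <- cand_pairs[ok, , drop = FALSE]
  d_base <- d_base[ok]
  if (!nrow(cand_pairs))
    gd_abort("gyredyn_pairing_failure",
             "no candidate satisfies the Watson-Crick distance criteria")

  # greedy assignment by ascending N1-N3 distance, ties by residue number
  ord <- order(d_base, s1$resno[cand_pairs$i], s2$resno[cand_pairs$j])
  used1 <- logical(nrow(s1)); used2 <- logical(nrow(s2))
  keep <- integer(0)
  for (k in ord) {
    i <- cand_pairs$i[k]; j <- cand_pairs$j[k]
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    keep <- c(keep, k)
  }
  i <- cand_pairs$i[keep]; j <- cand_pairs$j[keep]
  o <- order(s1$resno[i])
  i <- i[o]; j <- j[o]

  # antiparallelity via partner ordering along strand 1
  if (length(i) >= 2L && any(diff(s2$resno[j]) >= 0))
    gd_abort("gyredyn_pairing_failure",
             "strands are not locally antiparallel (partner numbers do not decrease along strand 1)")
  if (length(i) < 2L) {
    unpaired <- c(paste0(s1$chain[!used1], ":", s1$resno[!used1]),
                  paste0(s2$chain[!used2], ":", s2$resno[!used2]))
    gd_abort("gyredyn_pairing_failure", paste(
      "fewer than 2 base pairs found; unpaired residues:",
      paste(unpaired, collapse = ", ")))
  }

  pairs <- data.frame(
    chain1 = s1$chain[i], resnum1 = s1$resno[i], resname1 = s1$resid[i],
    chain2 = s2$chain[j], resnum2 = s2$resno[j], resname2 = s2$resid[j],
    purine_side = ifelse(s1$purine[i], "strand1", "strand2"),
    stringsAsFactors = FALSE)
  attr(pairs, "structure") <- structure
  pairs
}

#' Assign dyad-relative indices to detected base pairs
#'
#' The dyad pair receives index 0 and indices increase along strand 1 in the
#' direction of increasing residue number (5'->3'). `dyad_spec = "auto"`
#' places the dyad at the middle pair, position `(n-1)/2` (0-based) for odd
#' `n`; an even pair count demands an explicit dyad. An explicit dyad is an
#' author residue address, `list(chain =, resnum =)`, matching either
#' member of exactly one pair (this is how the two numbering conventions of
#' deposited models are reconciled: dyad at author residue 0 in
#' octasome-style models, at residue 73 in older nucleosome entries).
#'
#' @param pairs data frame from [detect_base_pairs()] (or the same shape),
#'   with the source structure attached as attribute, or passed via
#'   `structure`.
#' @param dyad_spec `"auto"` or `list(chain =, resnum =)`.
#' @param structure the source `gyre_structure`; defaults to
#'   `attr(pairs, "structure")`.
#' @return a `gyre_duplex`: list with `structure`, `pairs` (with
#'   `index_from_dyad` prepended), `dyad_position` (1-based list position of
#'   the dyad pair) and `length`.
#' @export
build_duplex <- function(pairs, dyad_spec = "auto", structure = NULL) {
  structure <- structure %||% attr(pairs, "structure")
  if (is.null(structure))
    gd_abort("gyredyn_dyad_error", "build_duplex needs the source structure")
  n <- nrow(pairs)
  if (identical(dyad_spec, "auto")) {
    if (n %% 2L == 0L)
      gd_abort("gyredyn_dyad_error",
               sprintf("%d pairs: even count has no automatic dyad; give dyad_spec", n))
    pos <- (n + 1L) %/% 2L
  } else {
    if (!is.list(dyad_spec) || is.null(dyad_spec$chain) || is.null(dyad_spec$resnum))
      gd_abort("gyredyn_dyad_error", "dyad_spec must be \"auto\" or list(chain=, resnum=)")
    hit <- which((pairs$chain1 == dyad_spec$chain & pairs$resnum1 == dyad_spec$resnum) |
                 (pairs$chain2 == dyad_spec$chain & pairs$resnum2 == dyad_spec$resnum))
    if (length(hit) != 1L)
      gd_abort("gyredyn_dyad_error", sprintf(
        "dyad residue %s:%s matches %d pairs (need exactly 1)",
        dyad_spec$chain, dyad_spec$resnum, length(hit)))
    pos <- hit
  }
  out <- cbind(index_from_dyad = seq_len(n) - pos, pairs)
  attr(out, "structure") <- NULL
  duplex_from_pairs(structure, out, dyad_position = pos)
}

# Shared constructor: resolve per-pair atom rows once so per-frame metric
# evaluation is a table lookup.
duplex_from_pairs <- function(str, pairs, dyad_position) {
  at <- str$atoms
  key <- paste(at$chain, at$resno, at$elety, sep = "\r")
  pur_chain <- ifelse(pairs$purine_side == "strand1", pairs$chain1, pairs$chain2)
  pur_resno <- ifelse(pairs$purine_side == "strand1", pairs$resnum1, pairs$resnum2)
  lookup <- list(
    n1   = match(paste(pur_chain, pur_resno, "N1", sep = "\r"), key),
    c1p1 = match(paste(pairs$chain1, pairs$resnum1, "C1'", sep = "\r"), key),
    c1p2 = match(paste(pairs$chain2, pairs$resnum2, "C1'", sep = "\r"), key))
  structure(list(structure = str, pairs = pairs,
                 dyad_position = dyad_position, length = nrow(pairs),
                 lookup = lookup),
            class = "gyre_duplex")
}

#' @export
print.gyre_duplex <- function(x, ...) {
  idx <- x$pairs$index_from_dyad
  cat(sprintf("<gyre_duplex> %d bp, dyad-relative indices %d..%d\n",
              x$length, min(idx), max(idx)))
  invisible(x)
}

# resolve a dyad-relative index to its pair row; classed errors
pair_row <- function(duplex, index) {
  r <- match(index, duplex$pairs$index_from_dyad)
  if (is.na(r))
    gd_abort("gyredyn_missing_pair",
             sprintf("no base pair at dyad-relative index %d", index))
  r
}

#' N1 coordinate of the purine at a dyad-relative index
#'
#' @param duplex a `gyre_duplex`.
#' @param index dyad-relative base-pair index (0 = dyad).
#' @param xyz optional n x 3 coordinate matrix overriding the structure's
#'   coordinates (used for per-frame evaluation).
#' @return 3-vector, Angstrom.
#' @export
purine_n1 <- function(duplex, index, xyz = NULL) {
  r <- pair_row(duplex, index)
  row <- duplex$lookup$n1[r]
  if (is.na(row))
    gd_abort("gyredyn_missing_atom", sprintf(
      "purine N1 atom absent for base pair at index %d", index))
  if (is.null(xyz)) xyz <- coords(duplex$structure)
  xyz[row, ]
}

# C1'-midpoint ("bp-center") reference point at a dyad-relative index
bp_center <- function(duplex, index, xyz = NULL) {
  r <- pair_row(duplex, index)
  r1 <- duplex$lookup$c1p1[r]
  r2 <- duplex$lookup$c1p2[r]
  if (is.na(r1) || is.na(r2))
    gd_abort("gyredyn_missing_atom", sprintf(
      "C1' atom absent for base pair at index %d", index))
  if (is.null(xyz)) xyz <- coords(duplex$structure)
  (xyz[r1, ] + xyz[r2, ]) / 2
}

#' Export the duplex pairing table
#'
#' @param duplex a `gyre_duplex`.
#' @param path optional CSV path; when given the table is written there.
#' @return the pairing table (columns `index_from_dyad`, `chain1`,
#'   `resnum1`, `resname1`, `chain2`, `resnum2`, `resname2`,
#'   `purine_side`), invisibly when written.
#' @export
duplex_table <- function(duplex, path = NULL) {
  tab <- duplex$pairs[, c("index_from_dyad", "chain1", "resnum1", "resname1",
                          "chain2", "resnum2", "resname2", "purine_side")]
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
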