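# Per-structure annotation: normalized b-factors, soft disorder, interfaces.

#' Normalized per-residue b-factor of a chain
#'
#' The raw B-factor of a residue is that of its Calpha atom. Per chain, the
#' mean and the population standard deviation (divisor N) over all observed
#' Calpha B-factors are subtracted and divided out, so every chain is scored
#' on a common scale regardless of resolution or crystal quality:
#' b_i = (B_i - <B>) / sigma. Chains with zero B variance get b = 0
#' everywhere; missing residues carry no value.
#'
#' @param chain a `ChainStructure`.
#' @return numeric vector of length `nchar(sequence)`, `NA` at positions
#'   without an observed Calpha.
#' @export
normalized_bfactor <- function(chain) {
  B <- chain$residues$bfactor
  obs <- !is.na(B)
  if (!any(obs)) stop("annotation error: chain has no observed Calpha B-factors")
  mu <- mean(B[obs])
  sigma <- sqrt(mean((B[obs] - mu)^2))
  b <- rep(NA_real_, length(B))
  if (sigma > 0) b[obs] <- (B[obs] - mu) / sigma else b[obs] <- 0
  b
}

#' Soft-disorder flags at a b-factor threshold
#'
#' Positions whose normalized b-factor is at least `theta`. In static mode
#' the raw B-factors are compared against an absolute threshold instead.
#'
#' @param b numeric vector of normalized b-factors (`NA` ignored).
#' @param theta threshold in sigma units (default 1).
#' @param B raw B-factors, used only when `static_b` is given.
#' @param static_b optional absolute B-factor threshold in A^2; when set,
#'   positions with `B >= static_b` are flagged instead.
#' @return sorted integer vector of flagged positions.
#' @export
soft_disorder_flags <- function(b, theta = 1, B = NULL, static_b = NULL) {
  if (!is.null(static_b)) {
    stopifnot(!is.null(B))
    return(which(!is.na(B) & B >= static_b))
  }
  which(!is.na(b) & b >= theta)
}

.ca_coords <- function(chain) {
  r <- chain$residues
  ok <- !r$is_missing & !is.na(r$x)
  list(pos = which(ok), xyz = cbind(r$x[ok], r$y[ok], r$z[ok]))
}

.cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
}

#' Protein-protein interface residues by Calpha distance
#'
#' Positions of chain `a` whose Calpha lies within `cutoff` (inclusive) of
#' any Calpha of chain `b`.
#'
#' @param a protein `ChainStructure` (positions reported on this chain).
#' @param b partner `ChainStructure`.
#' @param cutoff contact distance in Angstrom (default 5.0).
#' @return sorted integer vector of interface positions on `a`.
#' @export
protein_protein_interface <- function(a, b, cutoff = 5.0) {
  ca_a <- .ca_coords(a)
  ca_b <- .ca_coords(b)
  if (!length(ca_a$pos) || !length(ca_b$pos)) return(integer(0))
  d2 <- .cross_dist2(ca_a$xyz, ca_b$xyz)
  hit <- apply(d2 <= cutoff^2 + 1e-9, 1L, any)
  sort(ca_a$pos[hit])
}

.chain_sasa_atoms <- function(chain) {
  at <- chain$atoms
  if (is.null(at) || !nrow(at)) return(NULL)
  data.frame(
    x = at$x, y = at$y, z = at$z, element = at$element,
    group = paste(chain$chain_id, at$author_number, sep = ":"),
    stringsAsFactors = FALSE
  )
}

#' Protein-nucleic-acid interface residues by surface-area decrease
#'
#' A protein residue binds a DNA/RNA chain when its accessible surface area
#' in the protein+nucleic complex is lower than in the isolated protein by
#' more than `tol`. The relative normalization of RASA divides by a positive
#' per-residue constant, so a RASA decrease is equivalent to an ASA decrease.
#' Each nucleic partner chain is assessed separately and the results unioned,
#' so that occlusion by protein partners is never attributed to nucleic
#' binding.
#'
#' @param protein protein `ChainStructure`.
#' @param entry the `EntryStructure` containing it.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param tol minimum area decrease in A^2 to call a contact (default 0.1).
#' @return sorted integer vector of positions on `protein`.
#' @export
nucleic_interface <- function(protein, entry, probe = 1.4, tol = 0.1) {
  v <- unlist(.nucleic_partner_sets(protein, entry, probe, tol),
              use.names = FALSE)
  if (is.null(v)) integer(0) else sort(unique(v))
}

.nucleic_partner_sets <- function(protein, entry, probe = 1.4, tol = 0.1) {
  nuc <- Filter(function(ch) ch$molecule_class %in% c("dna", "rna") &&
                  !is.null(ch$atoms), entry$chains)
  nuc <- Filter(function(ch) ch$chain_id != protein$chain_id, nuc)
  if (!length(nuc)) return(list())
  pat <- .chain_sasa_atoms(protein)
  if (is.null(pat)) return(list())
  asa_alone <- sasa(pat, probe = probe)
  out <- list()
  for (ch in nuc) {
    comb <- rbind(pat, .chain_sasa_atoms(ch))
    asa_cplx <- sasa(comb, probe = probe)[names(asa_alone)]
    dec <- names(asa_alone)[asa_alone - asa_cplx > tol]
    keys <- sub("^[^:]*:", "", dec)
    pos <- sort(match(keys, protein$residues$author_number))
    pos <- pos[!is.na(pos)]
    if (length(pos)) out[[ch$chain_id]] <- pos
  }
  out
}

#' Annotate one protein chain within its entry
#'
#' Computes the full per-residue annotation used downstream: normalized
#' b-factors, soft-disorder sets at each threshold, missing positions,
#' interface positions split by partner chain (Calpha rule for protein
#' partners, surface-area rule for DNA/RNA partners), the number of direct
#' partners, and the bound/unbound label.
#'
#' @param entry an `EntryStructure`.
#' @param chain one of its protein `ChainStructure`s.
#' @param thetas soft-disorder thresholds in sigma units
#'   (default `c(0.5, 1, 2, 3)`).
#' @param cutoff Calpha contact cutoff in Angstrom (default 5.0).
#' @param probe SASA probe radius (default 1.4).
#' @param asa_tol minimum ASA decrease for a nucleic contact (default 0.1).
#' @param static_b optional absolute B-factor threshold (static variant).
#' @return object of class `ChainAnnotation`.
#' @export
annotate_chain <- function(entry, chain, thetas = c(0.5, 1, 2, 3),
                           cutoff = 5.0, probe = 1.4, asa_tol = 0.1,
                           static_b = NULL) {
  stopifnot(chain$molecule_class == "protein")
  L <- nchar(chain$sequence)
  b <- normalized_bfactor(chain)
  B <- chain$residues$bfactor
  soft <- lapply(thetas, function(th)
    soft_disorder_flags(b, th, B = B, static_b = static_b))
  names(soft) <- as.character(thetas)

  by_partner <- list()
  for (other in entry$chains) {
    if (identical(other$chain_id, chain$chain_id)) next
    if (other$molecule_class == "protein") {
      pos <- protein_protein_interface(chain, other, cutoff = cutoff)
      if (length(pos)) by_partner[[other$chain_id]] <- pos
    }
  }
  nuc_sets <- .nucleic_partner_sets(chain, entry, probe = probe, tol = asa_tol)
  for (cid in names(nuc_sets)) {
    by_partner[[cid]] <- sort(unique(c(by_partner[[cid]], nuc_sets[[cid]])))
  }

  interface <- sort(unique(unlist(by_partner, use.names = FALSE)))
  if (is.null(interface)) interface <- integer(0)

  structure(
    list(
      entry_id = entry$entry_id, chain_id = chain$chain_id,
      label = chain_label(entry$entry_id, chain$chain_id),
      length = L, sequence = chain$sequence,
      b = b,
      missing = which(chain$residues$is_missing),
      soft = soft,
      interface = interface,
      interface_by_partner = by_partner,
      partner_count = length(by_partner),
      bound = length(interface) > 0L,
      resolution = entry$resolution, r_value = entry$r_value
    ),
    class = "ChainAnnotation"
  )
}

#' @export
print.ChainAnnotation <- function(x, ...) {
  cat(sprintf(
    "<ChainAnnotation %s: L=%d, %d missing, %d interface, %s, %d partner(s)>\n",
    x$label, x$length, length(x$missing), length(x$interface),
    if (x$bound) "bound" else "unbound", x$partner_count))
  invisible(x)
}

#' Write a per-chain annotation table
#'
#' One row per sequence position with missing flag, normalized b-factor,
#' soft flags per threshold, interface flag and partner ids.
#'
#' @param ann a `ChainAnnotation`.
#' @param path output TSV file.
#' @return invisibly, the data.frame written.
#' @export
write_annotation_tsv <- function(ann, path) {
  L <- ann$length
  df <- data.frame(
    position = seq_len(L),
    aa = strsplit(ann$sequence, "")[[1]],
    missing = as.integer(seq_len(L) %in% ann$missing),
    b = ifelse(is.na(ann$b), "NA", sprintf("%.6f", ann$b)),
    stringsAsFactors = FALSE
  )
  for (th in names(ann$soft))
    df[[paste0("soft_", th)]] <- as.integer(seq_len(L) %in% ann$soft[[th]])
  df$interface <- as.integer(seq_len(L) %in% ann$interface)
  partner_of <- vapply(seq_len(L), function(p) {
    ids <- names(ann$interface_by_partner)[
      vapply(ann$interface_by_partner, function(s) p %in% s, logical(1))]
    paste(ids, collapse = ",")
  }, character(1))
  df$partners <- partner_of
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
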