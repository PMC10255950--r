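# Shared fixtures and independent oracles, all built in code.

# Brute-force stop/read-through counting oracle: iterate positions x reads.
# Kept deliberately naive and independent of count_rt_events.
brute_force_count <- function(reads, L, stop_offset = 0L,
                              exclude_region = NULL) {
  n_stop <- integer(L)
  n_rt <- integer(L)
  for (i in seq_len(nrow(reads))) {
    if ("mapped" %in% names(reads) && !reads$mapped[i]) next
    if ("strand" %in% names(reads) && reads$strand[i] == "-") next
    s <- reads$start[i]; e <- reads$end[i]
    if (s < 1L || e > L) next
    sp <- s + stop_offset
    in_excl <- !is.null(exclude_region) &&
      sp >= exclude_region[1] && sp <= exclude_region[2]
    for (p in seq_len(L)) {
      if (p == sp && !in_excl) n_stop[p] <- n_stop[p] + 1L
      if (p > s && p <= e) n_rt[p] <- n_rt[p] + 1L
    }
  }
  list(n_stop = n_stop, n_readthrough = n_rt)
}

toy_reference <- function(L = 20L, name = "toy") {
  transcript_reference(name, strrep("ACGU", ceiling(L / 4)) |>
                         substr(1, L))
}

# Fabricated reactivity profile with prescribed per-position values,
# for unit tests of the calling and differential layers.
fake_profile <- function(norm, raw = norm / 8, mask = !is.na(norm),
                         tb_concentration = 0.5, replicate_id = "r1",
                         context = "in_vitro", transcript = "tx") {
  L <- length(norm)
  structure(
    data.frame(position = seq_len(L),
               base = rep("A", L),
               n_stop_treated = NA_integer_,
               n_readthrough_treated = NA_integer_,
               n_stop_untreated = NA_integer_,
               n_readthrough_untreated = NA_integer_,
               p_stop_treated = NA_real_, p_stop_untreated = NA_real_,
               raw = raw, norm = norm, mask = mask,
               stringsAsFactors = FALSE),
    class = c("reactivity_profile", "data.frame"),
    transcript = transcript,
    condition = probing_condition(tb_concentration, replicate_id, context),
    norm_factor = NA_real_
  )
}

# Minimal fixed-width PDB writer for constructed structure fixtures.
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, alt = "", icode = "", elem = NULL) {
  elem <- elem %||% substr(trimws(name), 1, 1)
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resno, icode, x, y, z, occ, 0,
          elem)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_toy_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Backbone geometry table built directly from P coordinates.
geometry_from_coords <- function(coords, residue_numbers = NULL,
                                 chain = "A") {
  n <- nrow(coords)
  tab <- data.frame(chain = chain,
                    residue_number = residue_numbers %||% seq_len(n),
                    insert = "",
                    residue_name = "A",
                    x = coords[, 1], y = coords[, 2], z = coords[, 3],
                    d_n_n2 = NA_real_,
                    stringsAsFactors = FALSE)
  class(tab) <- c("backbone_geometry", "data.frame")
  tab
}

# Random rigid-body transform (rotation from QR of a Gaussian matrix).
random_rigid_transform <- function(coords) {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t(R %*% t(coords)) + matrix(rnorm(3, sd = 20), nrow(coords), 3,
                              byrow = TRUE)
}
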