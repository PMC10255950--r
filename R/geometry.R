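#' Extract backbone phosphate coordinates from a 3-D structure
#'
#' Reads a PDB or mmCIF file (dispatch on extension, via bio3d) and
#' returns one row per polymer residue of the requested chain, with
#' the phosphorus coordinate where the residue has a P atom
#' (5'-terminal residues typically do not). Alternate locations are
#' resolved to the highest-occupancy conformer (ties: first altloc
#' code alphabetically); multi-model files use `model_index`.
#'
#' @param structure path to a `.pdb`/`.ent` or `.cif` file, or an
#'   already-parsed `bio3d` structure object.
#' @param chain chain identifier.
#' @param model_index 1-based model number (NMR/multi-model files).
#' @return A data frame of class `backbone_geometry` with columns
#'   `chain`, `residue_number` (author numbering), `insert`,
#'   `residue_name`, `x`, `y`, `z` (P coordinate in angstroms, `NA`
#'   when the residue has no P atom) and `d_n_n2` (`NA` until
#'   [pn_pn2_distances()] fills it).
#' @export
extract_phosphates <- function(structure, chain, model_index = 1L) {
  pdb <- structure
  if (is.character(structure)) {
    if (!file.exists(structure)) stop("structure file not found: ", structure)
    pdb <- if (grepl("\\.cif(\\.gz)?$", structure, ignore.case = TRUE)) {
      bio3d::read.cif(structure, multi = TRUE, rm.alt = FALSE,
                      verbose = FALSE)
    } else {
      bio3d::read.pdb(structure, multi = TRUE, rm.alt = FALSE,
                      verbose = FALSE)
    }
  }
  if (!inherits(pdb, "pdb")) stop("not a parsable structure")
  atoms <- pdb$atom
  n_models <- nrow(pdb$xyz)
  model_index <- as.integer(model_index)
  if (model_index < 1L || model_index > n_models) {
    stop("model_index ", model_index, " out of range (structure has ",
         n_models, " model(s))")
  }
  # coordinates of the requested model, by atom
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
  sel <- atoms$type == "ATOM" & atoms$chain == chain
  if (!any(sel)) stop("chain '", chain, "' not found (or has no ATOM records)")
  a <- atoms[sel, , drop = FALSE]
  axyz <- xyz[which(sel), , drop = FALSE]
  ins <- a$insert
  ins[is.na(ins)] <- ""
  rkey <- paste(a$resno, ins, sep = "|")
  res <- !duplicated(rkey)
  tab <- data.frame(chain = chain,
                    residue_number = a$resno[res],
                    insert = ins[res],
                    residue_name = a$resid[res],
                    x = NA_real_, y = NA_real_, z = NA_real_,
                    d_n_n2 = NA_real_,
                    stringsAsFactors = FALSE)
  isP <- a$elety == "P"
  if (!any(isP)) {
    warning("chain '", chain, "' contains no phosphorus atoms")
  } else {
    occ <- a$o
    occ[is.na(occ)] <- 1
    alt <- a$alt
    alt[is.na(alt)] <- ""
    # altloc resolution: highest occupancy first, ties by altloc code
    pidx <- which(isP)
    ord <- pidx[order(-occ[pidx], alt[pidx])]
    keep <- ord[!duplicated(rkey[ord])]
    j <- match(rkey[keep], rkey[res])
    tab[j, c("x", "y", "z")] <- axyz[keep, , drop = FALSE]
  }
  tab <- tab[order(tab$residue_number, tab$insert), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("backbone_geometry", "data.frame")
  attr(tab, "model_index") <- model_index
  tab
}

#' Phosphate n to n+2 backbone-compression distances
#'
#' Fills `d_n_n2`: the Euclidean distance between the P atom of
#' residue n and the P atom of residue n+2. Compact tertiary modules
#' pinch every-other-phosphate pairs to well under helical values, so
#' small d(n, n+2) flags sharp backbone turns. A distance is defined
#' only when residues n, n+1 and n+2 are all present in the chain with
#' consecutive author numbers and no insertion codes, and both n and
#' n+2 have P coordinates -- chain breaks and engineered inserts never
#' produce spurious distances.
#'
#' @param table a `backbone_geometry` from [extract_phosphates()] (or
#'   built directly, e.g. by [ideal_aform_helix()]).
#' @return The same table with `d_n_n2` filled where defined.
#' @examples
#' helix <- ideal_aform_helix(12)
#' range(pn_pn2_distances(helix)$d_n_n2, na.rm = TRUE)
#' @export
pn_pn2_distances <- function(table) {
  stopifnot(inherits(table, "backbone_geometry"))
  tab <- table
  tab$d_n_n2 <- NA_real_
  plain <- tab$insert == "" | is.na(tab$insert)
  idx <- function(rn) {
    i <- which(tab$residue_number == rn & plain)
    if (length(i) == 1L) i else NA_integer_
  }
  for (i in seq_len(nrow(tab))) {
    if (!plain[i]) next
    n <- tab$residue_number[i]
    i1 <- idx(n + 1L); i2 <- idx(n + 2L)
    if (is.na(i1) || is.na(i2)) next
    if (is.na(tab$x[i]) || is.na(tab$x[i2])) next
    tab$d_n_n2[i] <- sqrt((tab$x[i] - tab$x[i2])^2 +
                          (tab$y[i] - tab$y[i2])^2 +
                          (tab$z[i] - tab$z[i2])^2)
  }
  tab
}

#' Compare backbone-compression distances between two site sets
#'
#' Summarizes d(n, n+2) over a set of probing-called positions and a
#' reference set (e.g. a canonical helix run) on the same structure,
#' and tests for a location difference with a two-sided Wilcoxon
#' rank-sum test. Transcript positions are mapped to author residue
#' numbers by a constant `offset` (residue = position + offset),
#' since construct numbering rarely matches deposited numbering.
#'
#' @param table a `backbone_geometry` with `d_n_n2` filled (run
#'   [pn_pn2_distances()] first; done automatically if all `d_n_n2`
#'   are `NA`).
#' @param site_positions,reference_positions integer transcript
#'   positions of the two sets.
#' @param offset added to positions to obtain author residue numbers.
#' @return A list of class `site_distance_comparison`:
#'   `sites`/`reference` (each min, max, mean, median, n, n_dropped,
#'   distances), `p_value`, `offset`.
#' @export
compare_site_distances <- function(table, site_positions,
                                   reference_positions, offset = 0L) {
  stopifnot(inherits(table, "backbone_geometry"))
  if (all(is.na(table$d_n_n2))) table <- pn_pn2_distances(table)
  pull <- function(positions, label) {
    rn <- as.integer(positions) + as.integer(offset)
    d <- table$d_n_n2[match(rn, table$residue_number)]
    dropped <- sum(is.na(d))
    d <- d[!is.na(d)]
    if (!length(d)) {
      stop("no defined d_n_n2 for any position in the ", label, " set")
    }
    list(min = min(d), max = max(d), mean = mean(d), median = median(d),
         n = length(d), n_dropped = dropped, distances = d)
  }
  s <- pull(site_positions, "site")
  r <- pull(reference_positions, "reference")
  p <- suppressWarnings(
    wilcox.test(s$distances, r$distances, alternative = "two.sided")$p.value
  )
  if (!is.finite(p)) {
    # degenerate (e.g. zero-variance) samples: identical distributions
    p <- if (isTRUE(all.equal(sort(s$distances), sort(r$distances)))) 1
         else NA_real_
  }
  structure(list(sites = s, reference = r, p_value = p,
                 offset = as.integer(offset)),
            class = "site_distance_comparison")
}

#' @export
print.site_distance_comparison <- function(x, ...) {
  f <- function(s, lab) {
    cat(sprintf(
      "  %-9s n=%d (%d dropped)  min %.2f  median %.2f  mean %.2f  max %.2f A\n",
      lab, s$n, s$n_dropped, s$min, s$median, s$mean, s$max))
  }
  cat("<site_distance_comparison> P(n)->P(n+2)\n")
  f(x$sites, "sites")
  f(x$reference, "reference")
  cat(sprintf("  Wilcoxon rank-sum p = %.3g\n", x$p_value))
  invisible(x)
}

#' Analytic ideal A-form helix phosphate trace
#'
#' Places one phosphorus per residue on the regular helix of A-form
#' RNA: rise 2.81 angstroms and twist 32.7 degrees per base step along
#' the helix axis, at a phosphate axial radius of 9.2 angstroms
#' (within the 8.7-9.5 angstrom range of fiber-diffraction A-form
#' models). Intra-strand d(n, n+2) for this geometry is
#' sqrt((2 rise)^2 + (2 r sin(twist))^2), about 11.2 angstroms --
#' inside the 9.6-12.5 angstrom helical reference band and far from
#' the compressed-turn regime. Used as the no-tertiary-structure
#' control for [compare_site_distances()] and in tests.
#'
#' @param n_residues number of consecutive residues.
#' @param rise axial rise per residue (angstroms).
#' @param twist rotation per residue (degrees).
#' @param radius phosphate distance from the helix axis (angstroms).
#' @param chain chain identifier for the output table.
#' @param first_residue author number of the first residue.
#' @return A `backbone_geometry` table (distances not yet filled).
#' @export
ideal_aform_helix <- function(n_residues = 20L, rise = 2.81,
                              twist = 32.7, radius = 9.2, chain = "A",
                              first_residue = 1L) {
  stopifnot(n_residues >= 1L)
  k <- seq_len(n_residues) - 1L
  theta <- k * twist * pi / 180
  tab <- data.frame(chain = chain,
                    residue_number = first_residue + k,
                    insert = "",
                    residue_name = rep(c("A", "U", "G", "C"),
                                       length.out = n_residues),
                    x = radius * cos(theta),
                    y = radius * sin(theta),
                    z = rise * k,
                    d_n_n2 = NA_real_,
                    stringsAsFactors = FALSE)
  class(tab) <- c("backbone_geometry", "data.frame")
  attr(tab, "model_index") <- 1L
  tab
}

#' Write a backbone geometry table as TSV
#'
#' @param table a `backbone_geometry`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_geometry_tsv <- function(table, path) {
  stopifnot(inherits(table, "backbone_geometry"))
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
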