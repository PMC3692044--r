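# Free-energy features of the miRNA-target interaction, computed on the
# built-in simplified nearest-neighbor backend (see src/thermo.cpp). All
# energies are kcal/mol at 37 C; the no-interaction convention caps
# hybridization energies at 0 (a destabilizing duplex means no binding).

.thermo_env <- new.env(parent = emptyenv())

#' Load the nearest-neighbor energy table
#'
#' Reads the stack free energies (Watson-Crick and G:U wobble, 37 C) and
#' global parameters (duplex initiation, weak-end penalty, affine loop
#' penalty, maximum loop size, single-strand pair penalty) from the TSV
#' resource shipped with the package, or from a user-supplied file of the
#' same layout.
#'
#' @param path TSV path; default is the shipped table.
#' @return list with `stacks` (6x6 matrix, pair order AU,UA,CG,GC,GU,UG)
#'   and the named `params`.
#' @export
load_nn_table <- function(path = system.file("extdata", "nn_stacks.tsv",
                                             package = "mirtarscan")) {
  tab <- read_tsv_table(path)
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  st <- tab[tab$type == "stack", ]
  S <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  S[cbind(match(st$key1, pairs), match(st$key2, pairs))] <- st$value
  if (anyNA(S)) stop("incomplete stack table in ", path)
  pr <- tab[tab$type == "param", ]
  params <- stats::setNames(pr$value, pr$key1)
  needed <- c("duplex_init", "au_end", "loop_base", "loop_per_nt",
              "max_loop", "ss_pair_penalty")
  if (!all(needed %in% names(params))) {
    stop("missing parameters in ", path, ": ",
         paste(setdiff(needed, names(params)), collapse = ", "))
  }
  list(stacks = S, params = params)
}

nn_table <- function() {
  if (is.null(.thermo_env$nn)) .thermo_env$nn <- load_nn_table()
  .thermo_env$nn
}

duplex_energies <- function(a, b, nn = nn_table()) {
  p <- nn$params
  duplex_dp(seq_to_int(a), seq_to_int(b), nn$stacks,
            p[["duplex_init"]], p[["au_end"]], p[["loop_base"]],
            p[["loop_per_nt"]], as.integer(p[["max_loop"]]), RT_37C)
}

#' Minimum free energy of intermolecular hybridization
#'
#' MFE over all intermolecular duplex structures (stacked helices separated
#' by internal loops/bulges; no intramolecular pairs), 0.0 when no
#' stabilizing duplex exists. `N` never pairs.
#'
#' @param mirna,target_region RNA strings, 5' to 3'.
#' @return energy in kcal/mol, always <= 0.
#' @export
dg_duplex <- function(mirna, target_region) {
  if (nchar(mirna) == 0 || nchar(target_region) == 0) {
    stop("both sequences must be nonempty")
  }
  duplex_energies(mirna, target_region)$dg_duplex
}

#' Ensemble hybridization free energy
#'
#' `-RT ln Z` over all intermolecular structures of the pair, the empty
#' (unbound) structure included with weight 1, so the value is 0.0 when no
#' pairing is possible and is always <= the duplex MFE.
#'
#' @inheritParams dg_duplex
#' @export
dg_binding <- function(mirna, target_region) {
  if (nchar(mirna) == 0 || nchar(target_region) == 0) {
    stop("both sequences must be nonempty")
  }
  duplex_energies(mirna, target_region)$dg_binding
}

site_region <- function(utr, site, upstream = 0) {
  a <- max(0L, site$start - as.integer(upstream))
  substr(utr, a + 1L, site$end)
}

#' Duplex and ensemble energies restricted to the seed region
#'
#' Same computations as [dg_duplex()] / [dg_binding()] with the miRNA
#' restricted to positions 1-8 and the target restricted to the matched
#' site region.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param utr UTR sequence.
#' @param site one site (a row of [find_sites()] output, as a list or
#'   one-row data.frame).
#' @export
dg_seed_duplex <- function(mirna, utr, site) {
  dg_duplex(substr(mirna, 1, 8), site_region(utr, site))
}

#' @rdname dg_seed_duplex
#' @export
dg_seed_binding <- function(mirna, utr, site) {
  dg_binding(substr(mirna, 1, 8), site_region(utr, site))
}

#' Site accessibility opening energy
#'
#' `dg_open = G_constrained - G_unconstrained >= 0`, where both terms are
#' single-strand ensemble free energies of the window
#' `[site$start - flank, site$end + flank)` clamped to the UTR, and the
#' constraint forces every site position unpaired.
#'
#' @param utr UTR sequence.
#' @param site a site on the UTR.
#' @param flank window extension on each side, nt.
#' @return kcal/mol, >= 0.
#' @export
dg_open <- function(utr, site, flank = 70) {
  L <- nchar(utr)
  a <- max(0L, site$start - as.integer(flank))
  b <- min(L, site$end + as.integer(flank))
  win <- seq_to_int(substr(utr, a + 1L, b))
  mask <- rep(FALSE, length(win))
  mask[(site$start - a + 1L):(site$end - a)] <- TRUE
  nn <- nn_table()
  g_un <- ss_ensemble_energy(win, rep(FALSE, length(win)), nn$stacks,
                             nn$params[["ss_pair_penalty"]], RT_37C, 3L)
  g_con <- ss_ensemble_energy(win, mask, nn$stacks,
                              nn$params[["ss_pair_penalty"]], RT_37C, 3L)
  max(0, g_con - g_un)
}

#' Total interaction energy
#'
#' The sum of the duplex hybridization energy and the opening energy.
#'
#' @param dg_duplex,dg_open energies in kcal/mol.
#' @export
dg_total <- function(dg_duplex, dg_open) dg_duplex + dg_open

#' All free-energy features of one site
#'
#' The duplex energies use the site region extended by `upstream` nt on the
#' 5' side of the seed match so that 3' pairing of the miRNA can form.
#'
#' @inheritParams dg_open
#' @param mirna miRNA sequence.
#' @param upstream nt of UTR added upstream of the site for the full-length
#'   duplex energies.
#' @return named list: `dg_duplex, dg_binding, dg_seed_duplex,
#'   dg_seed_binding, dg_open, dg_total` (kcal/mol).
#' @export
site_energies <- function(mirna, utr, site, flank = 70, upstream = 15) {
  region <- site_region(utr, site, upstream = upstream)
  dd <- duplex_energies(mirna, region)
  dgo <- dg_open(utr, site, flank = flank)
  list(dg_duplex = dd$dg_duplex,
       dg_binding = dd$dg_binding,
       dg_seed_duplex = dg_seed_duplex(mirna, utr, site),
       dg_seed_binding = dg_seed_binding(mirna, utr, site),
       dg_open = dgo,
       dg_total = dg_total(dd$dg_duplex, dgo))
}
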