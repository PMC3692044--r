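# End-to-end pipeline: scan all miRNA x UTR pairs, compute the feature
# report at site or pair level, transform to percentiles, filter, sort and
# export. These functions back the command-line interface.

#' Scan UTRs for seed-match sites of a set of miRNAs
#'
#' @param utr_fasta,mirna_fasta FASTA paths (or named character vectors of
#'   sequences).
#' @param out_tsv optional TSV output path.
#' @param out_bed optional BED6 output path.
#' @return data.frame of sites, ordered by (utr, mirna, start).
#' @export
run_scan <- function(utr_fasta, mirna_fasta, out_tsv = NULL, out_bed = NULL) {
  utrs <- if (is.character(utr_fasta) && length(utr_fasta) == 1 &&
              file.exists(utr_fasta)) read_fasta(utr_fasta) else utr_fasta
  mirnas <- if (is.character(mirna_fasta) && length(mirna_fasta) == 1 &&
                file.exists(mirna_fasta)) read_fasta(mirna_fasta) else mirna_fasta
  if (length(utrs) == 0 || length(mirnas) == 0) {
    warning("empty input; no sites to report")
    sites <- empty_sites()
  } else {
    parts <- list()
    for (u in names(utrs)) for (m in names(mirnas)) {
      parts[[paste(u, m)]] <- find_sites(utrs[[u]], mirnas[[m]], u, m)
    }
    sites <- do.call(rbind, parts)
    sites <- sites[order(sites$utr_id, sites$mirna, sites$start), ,
                   drop = FALSE]
    rownames(sites) <- NULL
  }
  if (!is.null(out_tsv)) {
    write.table(sites, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out_bed)) write_bed(sites, out_bed)
  sites
}

# all features of the sites of one utr/mirna pair (site-level data.frame)
pair_site_features <- function(utr, mirna, sites, tree = NULL, aln = NULL,
                               flank = 70, upstream = 15) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    site <- as.list(sites[i, ])
    en <- site_energies(mirna, utr, site, flank = flank, upstream = upstream)
    cons <- list(bls = NA_real_, phylop_score = NA_real_)
    if (!is.null(tree) && !is.null(aln)) {
      present <- site_presence(aln, site, seed_match(mirna, "2-7"))
      cons$bls <- bls(tree, intersect(present, tree$tip.label))
      ph <- tryCatch(
        suppressWarnings(phylop_score(tree, site_columns(aln, site))),
        error = function(e) NULL)
      cons$phylop_score <- if (is.null(ph)) NA_real_ else ph$phylop_score
    }
    data.frame(site[c("utr_id", "mirna", "start", "end", "site_type")],
               as.data.frame(en),
               au_content = au_content(utr, site),
               utr_position = utr_position(utr, site),
               three_prime_pairing = three_prime_pairing(mirna, utr, site),
               bls = cons$bls, phylop_score = cons$phylop_score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compute the full feature report
#'
#' Scans every miRNA x UTR pair, computes site-level features, aggregates
#' them to pair level and appends the pair-level over-representation
#' probabilities and (when a model is given) the predicted repression
#' score.
#'
#' @inheritParams run_scan
#' @param model optional `mirmap_model` used for the `mirmap_score` column.
#' @param tree optional `phylo` tree (with `aln`) for conservation
#'   features.
#' @param aln optional [species_alignment()]; sites are located on its
#'   reference species' ungapped sequence, which must match the input UTR
#'   of the same id.
#' @param view `"pair"` (default) or `"site"`.
#' @param flank,upstream thermodynamic windows (see [site_energies()]).
#' @return data.frame, one row per pair or per site.
#' @export
compute_report <- function(utr_fasta, mirna_fasta, model = NULL,
                           tree = NULL, aln = NULL,
                           view = c("pair", "site"),
                           flank = 70, upstream = 15) {
  view <- match.arg(view)
  utrs <- if (is.character(utr_fasta) && length(utr_fasta) == 1 &&
              file.exists(utr_fasta)) read_fasta(utr_fasta) else utr_fasta
  mirnas <- if (is.character(mirna_fasta) && length(mirna_fasta) == 1 &&
                file.exists(mirna_fasta)) read_fasta(mirna_fasta) else mirna_fasta
  if (!is.null(tree) && is.null(aln)) {
    warning("tree given without alignment; conservation features skipped")
    tree <- NULL
  }
  if (is.null(tree) && !is.null(aln)) {
    warning("alignment given without tree; conservation features skipped")
    aln <- NULL
  }
  out <- list()
  for (u in names(utrs)) {
    for (m in names(mirnas)) {
      sites <- find_sites(utrs[[u]], mirnas[[m]], u, m)
      if (nrow(sites) == 0) next
      aln_u <- if (!is.null(aln) &&
                   alignment_ref_seq(aln) == utrs[[u]]) aln else NULL
      sf <- pair_site_features(utrs[[u]], mirnas[[m]], sites,
                               tree = if (is.null(aln_u)) NULL else tree,
                               aln = aln_u, flank = flank,
                               upstream = upstream)
      if (view == "site") {
        out[[paste(u, m)]] <- sf
      } else {
        agg <- aggregate_pair(sf)
        pe <- pover_feature(utrs[[u]], mirnas[[m]], "exact")
        pb <- pover_feature(utrs[[u]], mirnas[[m]], "binomial")
        row <- data.frame(utr_id = u, mirna = m,
                          t(agg),
                          pover_binomial = pb$p_over,
                          pover_exact = pe$p_over,
                          seed_matches = pe$observed_n,
                          stringsAsFactors = FALSE)
        out[[paste(u, m)]] <- row
      }
    }
  }
  if (length(out) == 0) return(NULL)
  rep_ <- do.call(rbind, out)
  rownames(rep_) <- NULL
  if (!is.null(model) && view == "pair") {
    have <- intersect(names(model$coefficients), names(rep_))
    usable <- have[colSums(is.na(rep_[have])) == 0]
    if (length(usable) < length(model$coefficients)) {
      red <- list(intercept = model$intercept,
                  coefficients = model$coefficients[usable])
      class(red) <- "mirmap_model"
      rep_$mirmap_score <- predict_repression(red, rep_)
      rep_$reduced_model <- TRUE
    } else {
      rep_$mirmap_score <- predict_repression(model, rep_)
      rep_$reduced_model <- FALSE
    }
  }
  rep_
}

apply_percentiles <- function(report, background = NULL,
                              directions = default_directions()) {
  feats <- intersect(feature_registry(), names(report))
  for (f in feats) {
    bg <- if (!is.null(background) && f %in% names(background)) {
      background[[f]]
    } else report[[f]]
    bg <- bg[!is.na(bg)]
    if (length(bg) == 0) next
    v <- report[[f]]
    ok <- !is.na(v)
    report[[f]][ok] <- percentile_transform(v[ok], bg, f, directions)
  }
  report
}

#' Score miRNA-UTR pairs and export the report
#'
#' The full pipeline behind the `score` command: feature computation,
#' optional percentile conversion, per-feature min/max filtering,
#' multicolumn sorting (by predicted repression strength by default) and
#' CSV export.
#'
#' @inheritParams compute_report
#' @param mode `"raw"` or `"percentile"`.
#' @param background optional named list of per-feature background samples
#'   (e.g. from [run_background()]); by default the result set itself is
#'   the background.
#' @param sort_by character vector of columns for multicolumn ordered
#'   sorting; default sorts by `mirmap_score` (strongest repression first)
#'   when available.
#' @param min_filters,max_filters named numeric vectors; rows with a
#'   feature outside `[min, max]` are dropped (applied after the mode
#'   transform, before output).
#' @param out_csv optional CSV output path.
#' @export
run_score <- function(utr_fasta, mirna_fasta, model = demo_model(),
                      tree = NULL, aln = NULL,
                      view = c("pair", "site"), mode = c("raw", "percentile"),
                      background = NULL, sort_by = NULL,
                      min_filters = NULL, max_filters = NULL,
                      flank = 70, upstream = 15, out_csv = NULL) {
  view <- match.arg(view)
  mode <- match.arg(mode)
  report <- compute_report(utr_fasta, mirna_fasta, model = model,
                           tree = tree, aln = aln, view = view,
                           flank = flank, upstream = upstream)
  if (is.null(report)) {
    report <- data.frame()
    if (!is.null(out_csv)) write_csv_report(report, out_csv)
    return(report)
  }
  if (mode == "percentile") {
    report <- apply_percentiles(report, background)
  }
  for (f in names(min_filters)) {
    if (f %in% names(report)) report <- report[!is.na(report[[f]]) &
                                                 report[[f]] >= min_filters[[f]], ,
                                               drop = FALSE]
  }
  for (f in names(max_filters)) {
    if (f %in% names(report)) report <- report[!is.na(report[[f]]) &
                                                 report[[f]] <= max_filters[[f]], ,
                                               drop = FALSE]
  }
  if (is.null(sort_by)) {
    if ("mirmap_score" %in% names(report)) {
      # strongest predicted repression first: most negative raw score,
      # or highest percentile
      decreasing <- mode == "percentile"
      report <- report[order(report$mirmap_score,
                             decreasing = decreasing), , drop = FALSE]
    }
  } else {
    keys <- report[intersect(sort_by, names(report))]
    if (ncol(keys) > 0) report <- report[do.call(order, keys), , drop = FALSE]
  }
  rownames(report) <- NULL
  if (!is.null(out_csv)) write_csv_report(report, out_csv)
  report
}

#' Fit the linear model from a training table
#'
#' @param training_tsv TSV with feature columns and a `log2fc` response
#'   column.
#' @param out_model optional path for the serialized model.
#' @return a `mirmap_model`.
#' @export
run_fit <- function(training_tsv, out_model = NULL) {
  tab <- read_tsv_table(training_tsv)
  if (!"log2fc" %in% names(tab)) {
    stop("training table must have a 'log2fc' response column")
  }
  y <- tab$log2fc
  X <- tab[setdiff(names(tab), c("log2fc", "utr_id", "mirna"))]
  model <- fit_linear_model(X, y)
  if (!is.null(out_model)) write_model(model, out_model)
  model
}

#' Compute a percentile background over a sequence set
#'
#' Scans and scores all pairs of the input set and collects each feature's
#' raw values as the background sample for [percentile_transform()].
#'
#' @inheritParams compute_report
#' @param out_tsv optional long-format TSV (`feature, value`).
#' @return named list of numeric vectors.
#' @export
run_background <- function(utr_fasta, mirna_fasta, model = demo_model(),
                           tree = NULL, aln = NULL, out_tsv = NULL) {
  report <- compute_report(utr_fasta, mirna_fasta, model = model,
                           tree = tree, aln = aln, view = "pair")
  feats <- intersect(feature_registry(), names(report))
  bg <- lapply(stats::setNames(feats, feats), function(f) {
    v <- report[[f]]; v[!is.na(v)]
  })
  if (!is.null(out_tsv)) {
    long <- do.call(rbind, lapply(names(bg), function(f) {
      if (length(bg[[f]]) == 0) return(NULL)
      data.frame(feature = f, value = bg[[f]])
    }))
    write.table(long, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bg
}

#' Read a background TSV written by [run_background()]
#' @param path long-format TSV (`feature, value`).
#' @export
read_background <- function(path) {
  tab <- read_tsv_table(path)
  split(tab$value, tab$feature)
}
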