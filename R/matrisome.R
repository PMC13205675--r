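.matrisome_categories <- data.frame(
  category = c("collagens", "proteoglycans", "glycoproteins",
               "ECM regulators", "ECM-affiliated", "secreted factors"),
  division = c(rep("core matrisome", 3L), rep("matrisome-associated", 3L)),
  stringsAsFactors = FALSE
)

#' Matrisome divisions and categories
#'
#' The matrisome is split into the core matrisome (collagens, proteoglycans,
#' ECM glycoproteins) and matrisome-associated proteins (ECM regulators,
#' ECM-affiliated proteins, secreted factors).
#'
#' @return `data.frame` with columns `category`, `division`.
#' @export
matrisome_categories <- function() .matrisome_categories

#' Load a matrisome reference table
#'
#' Reads a gene-to-category map (MatrisomeDB-style columns `identifier`,
#' `division`, `category`), validates that every category belongs to its
#' division, and case-folds identifiers. Duplicate identifiers (after
#' case-folding) and unknown categories are errors.
#'
#' @param path CSV path; defaults to the bundled synthetic test fixture
#'   (a small made-up gene set, not a published atlas).
#' @return Object of class `matrisome_reference`: `entries` (data.frame),
#'   `version`.
#' @export
load_reference <- function(path = system.file("extdata", "matrisome_reference_synthetic.csv",
                                              package = "ovamat")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("identifier", "division", "category")
  if (!all(need %in% names(tab))) {
    stop("load_reference: need columns identifier, division, category", call. = FALSE)
  }
  if (!nrow(tab)) stop("load_reference: empty reference", call. = FALSE)
  bad_cat <- setdiff(unique(tab$category), .matrisome_categories$category)
  if (length(bad_cat)) {
    stop("load_reference: unknown categor(ies): ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  expected_div <- .matrisome_categories$division[
    match(tab$category, .matrisome_categories$category)]
  if (any(tab$division != expected_div)) {
    off <- tab$identifier[tab$division != expected_div]
    stop("load_reference: division inconsistent with category for: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  tab$identifier <- tolower(tab$identifier)
  dup <- tab$identifier[duplicated(tab$identifier)]
  if (length(dup)) {
    stop("load_reference: duplicate identifiers after case-folding: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  structure(list(entries = tab, version = basename(path)),
            class = "matrisome_reference")
}

#' Categorize an identifier list against the matrisome reference
#'
#' Case-insensitive exact symbol matching: matched identifiers are counted
#' per matrisome category; unmatched ones are labelled non-matrisome.
#' Duplicates in the input are collapsed before counting and reported.
#'
#' @param ids Character vector of gene/protein identifiers (non-empty).
#' @param ref A `matrisome_reference`.
#' @return Object of class `annotation_result`: `counts` (named, six
#'   categories), `percentages` (of the matrisome total), `non_matrisome`,
#'   `input_size` (after deduplication), `n_duplicates`,
#'   `assignments` (data.frame identifier/category).
#' @export
annotate_list <- function(ids, ref) {
  stopifnot(inherits(ref, "matrisome_reference"))
  if (!length(ids)) stop("annotate_list: empty identifier list", call. = FALSE)
  ids <- tolower(as.character(ids))
  n_dup <- sum(duplicated(ids))
  ids <- unique(ids)
  cat_of <- ref$entries$category[match(ids, ref$entries$identifier)]
  cat_of[is.na(cat_of)] <- "non-matrisome"
  cats <- .matrisome_categories$category
  counts <- vapply(cats, function(cc) sum(cat_of == cc), integer(1))
  non_matrisome <- sum(cat_of == "non-matrisome")
  total_matrisome <- sum(counts)
  pct <- if (total_matrisome > 0) 100 * counts / total_matrisome else counts * NA_real_
  structure(list(counts = counts, percentages = pct,
                 non_matrisome = non_matrisome, input_size = length(ids),
                 n_duplicates = n_dup,
                 assignments = data.frame(identifier = ids, category = cat_of,
                                          stringsAsFactors = FALSE)),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> %d identifiers: %d matrisome, %d non-matrisome\n",
              x$input_size, sum(x$counts), x$non_matrisome))
  for (i in seq_along(x$counts)) {
    cat(sprintf("  %-18s %4d (%5.1f%% of matrisome)\n",
                names(x$counts)[i], x$counts[i], x$percentages[i]))
  }
  invisible(x)
}

#' Venn region counts for species identifier sets
#'
#' Exact set algebra over up to `s` identifier sets: every one of the
#' `2^s - 1` membership patterns (regions of the Venn diagram) is counted
#' and its members reported. Identifiers are case-folded before comparison.
#'
#' @param lists Named list of character vectors (one per species/dataset).
#' @return List: `regions` (data.frame with one row per region: the
#'   membership pattern, a label like `"human&mouse"`, and `count`),
#'   `membership` (data.frame identifier/region label), `union_size`.
#' @export
overlap_sets <- function(lists) {
  if (!is.list(lists) || length(lists) < 1L) {
    stop("overlap_sets: need a named list of identifier vectors", call. = FALSE)
  }
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    stop("overlap_sets: every set needs a name", call. = FALSE)
  }
  sets <- lapply(lists, function(v) unique(tolower(as.character(v))))
  u <- sort(unique(unlist(sets)))
  s <- length(sets)
  memb <- vapply(sets, function(v) u %in% v, logical(length(u)))
  if (length(u) == 1L) memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, names(sets)))
  pattern_id <- as.integer(memb %*% 2^(seq_len(s) - 1))
  patterns <- lapply(seq_len(2^s - 1L), function(p) as.logical(bitwAnd(p, 2^(seq_len(s) - 1)) > 0))
  labels <- vapply(patterns, function(pt) paste(names(sets)[pt], collapse = "&"), character(1))
  counts <- vapply(seq_len(2^s - 1L), function(p) sum(pattern_id == p), integer(1))
  region_label <- labels[pattern_id]
  list(regions = data.frame(pattern = seq_len(2^s - 1L), label = labels,
                            count = counts, stringsAsFactors = FALSE),
       membership = data.frame(identifier = u, region = region_label,
                               stringsAsFactors = FALSE),
       union_size = length(u))
}

#' Filter differentially expressed genes
#'
#' Keeps records with `|log2fc| > fc_threshold` and `p < p_threshold`
#' (strict inequalities on both boundaries) and summarizes up/down counts.
#'
#' @param table `data.frame` with columns `log2fc` and `p` (an `identifier`
#'   column is carried through if present).
#' @param fc_threshold Absolute log2 fold-change cutoff (default 1).
#' @param p_threshold P-value cutoff (default 0.05).
#' @return List: `subset` (surviving rows), `n_up`, `n_down`, `n_total`.
#' @export
deg_filter <- function(table, fc_threshold = 1.0, p_threshold = 0.05) {
  stopifnot(is.data.frame(table), all(c("log2fc", "p") %in% names(table)))
  if (any(table$p < 0 | table$p > 1, na.rm = TRUE)) {
    stop("deg_filter: p-values must lie in [0, 1]", call. = FALSE)
  }
  keep <- abs(table$log2fc) > fc_threshold & table$p < p_threshold
  keep[is.na(keep)] <- FALSE
  sub <- table[keep, , drop = FALSE]
  list(subset = sub,
       n_up = sum(sub$log2fc > 0), n_down = sum(sub$log2fc < 0),
       n_total = nrow(sub))
}

#' Nine-quadrant mRNA-protein concordance
#'
#' Classifies each gene by its joint significance state on the two axes:
#' per axis, `down` when `log2fc < -t` and `p < alpha`, `up` when
#' `log2fc > t` and `p < alpha`, `unchanged` otherwise. Quadrants are
#' numbered `3 * mRNA_state + protein_state + 1` with states down = 0,
#' unchanged = 1, up = 2, so quadrant 1 is down/down, 5 unchanged/unchanged
#' and 9 up/up. The Pearson correlation of the two fold-change vectors is
#' computed over all supplied pairs (with `n` reported), since restricting
#' to significant genes is a separate, explicit choice.
#'
#' @param pairs `data.frame` with columns `log2fc_mrna`, `p_mrna`,
#'   `log2fc_protein`, `p_protein`.
#' @param fc_threshold,p_threshold Axis-state thresholds (defaults follow
#'   the DEG criterion: 1.0 and 0.05, strict).
#' @return Object of class `quadrant_assignment`: `quadrant` (integer
#'   vector), `counts` (length 9), `pearson_r`, `n`.
#' @export
nine_quadrant <- function(pairs, fc_threshold = 1.0, p_threshold = 0.05) {
  need <- c("log2fc_mrna", "p_mrna", "log2fc_protein", "p_protein")
  stopifnot(is.data.frame(pairs), all(need %in% names(pairs)))
  axis_state <- function(fc, p) {
    st <- rep(1L, length(fc))  # unchanged
    st[fc < -fc_threshold & p < p_threshold] <- 0L
    st[fc > fc_threshold & p < p_threshold] <- 2L
    st
  }
  sm <- axis_state(pairs$log2fc_mrna, pairs$p_mrna)
  sp <- axis_state(pairs$log2fc_protein, pairs$p_protein)
  q <- 3L * sm + sp + 1L
  counts <- vapply(1:9, function(i) sum(q == i), integer(1))
  r <- pearson_r(pairs$log2fc_mrna, pairs$log2fc_protein)
  structure(list(quadrant = q, counts = counts, pearson_r = r, n = nrow(pairs)),
            class = "quadrant_assignment")
}

#' @export
print.quadrant_assignment <- function(x, ...) {
  cat(sprintf("<quadrant_assignment> n = %d, Pearson r = %.4f\n", x$n, x$pearson_r))
  m <- matrix(x$counts, 3, 3, byrow = TRUE,
              dimnames = list(mRNA = c("down", "unchanged", "up"),
                              protein = c("down", "unchanged", "up")))
  print(m)
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper over the standard product-moment formula; errors
#' on fewer than 3 pairs or zero variance, where the coefficient is
#' undefined.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_r: x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("pearson_r: need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r: undefined for zero-variance input", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}
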