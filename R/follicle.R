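#' Construct a follicle record
#'
#' Morphology-annotated follicle as scored on H&E sections: granulosa layer
#' count and shape, antrum presence, oocyte-nucleus visibility (the
#' inclusion criterion), health, and optional oocyte/follicle diameters.
#'
#' @param id Record identifier.
#' @param oocyte_diameter,follicle_diameter Diameters in micrometres
#'   (optional, `NA` if unmeasured; must be > 0 when present).
#' @param nucleus_visible Oocyte nucleus visible in the section (inclusion
#'   criterion).
#' @param granulosa_layers Number of granulosa layers (>= 0).
#' @param granulosa_shape One of `"flattened"`, `"mixed_cuboidal_squamous"`,
#'   `"cuboidal"`.
#' @param antrum_present Fluid-filled antrum present.
#' @param healthy Morphologically healthy (non-atretic).
#' @return One-row `data.frame` with the `FollicleRecord` columns.
#' @export
follicle_record <- function(id, oocyte_diameter = NA_real_,
                            follicle_diameter = NA_real_,
                            nucleus_visible = TRUE, granulosa_layers = 1L,
                            granulosa_shape = "flattened",
                            antrum_present = FALSE, healthy = TRUE) {
  shapes <- c("flattened", "mixed_cuboidal_squamous", "cuboidal")
  if (!granulosa_shape %in% shapes) {
    stop("follicle_record: granulosa_shape must be one of ", paste(shapes, collapse = ", "),
         call. = FALSE)
  }
  for (d in c(oocyte_diameter, follicle_diameter)) {
    if (!is.na(d) && d <= 0) stop("follicle_record: diameters must be > 0", call. = FALSE)
  }
  if (granulosa_layers < 0) stop("follicle_record: granulosa_layers must be >= 0", call. = FALSE)
  data.frame(id = id, oocyte_diameter = as.numeric(oocyte_diameter),
             follicle_diameter = as.numeric(follicle_diameter),
             nucleus_visible = isTRUE(nucleus_visible),
             granulosa_layers = as.integer(granulosa_layers),
             granulosa_shape = granulosa_shape,
             antrum_present = isTRUE(antrum_present),
             healthy = isTRUE(healthy),
             stringsAsFactors = FALSE)
}

#' Stage a follicle from its morphology
#'
#' Rule-based staging with fixed precedence: records without a visible
#' oocyte nucleus are `excluded`; an antrum makes the follicle `antral`;
#' otherwise flattened (pre-)granulosa means `primordial`, a single mixed
#' cuboidal/squamous layer means `primary`, and two or more cuboidal layers
#' mean `secondary`. A contradictory combination (e.g. an antrum over a
#' single flattened layer) is classified antral with a consistency warning.
#'
#' @param rec One-row `data.frame` as from [follicle_record()], or a
#'   multi-row table (then a vector of labels is returned).
#' @return Character stage label(s): one of `"primordial"`, `"primary"`,
#'   `"secondary"`, `"antral"`, `"excluded"`.
#' @export
classify_follicle <- function(rec) {
  stopifnot(is.data.frame(rec))
  vapply(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]
    if (!isTRUE(r$nucleus_visible)) return("excluded")
    if (isTRUE(r$antrum_present)) {
      if (r$granulosa_shape == "flattened" && r$granulosa_layers <= 1L) {
        warning(sprintf("follicle %s: antrum with a single flattened layer is contradictory; classified antral",
                        r$id))
      }
      return("antral")
    }
    if (r$granulosa_shape == "flattened") return("primordial")
    if (r$granulosa_shape == "mixed_cuboidal_squamous" && r$granulosa_layers == 1L) {
      return("primary")
    }
    if (r$granulosa_shape == "cuboidal" && r$granulosa_layers >= 2L) return("secondary")
    # single cuboidal layer: transitional, scored with the primary follicles
    if (r$granulosa_shape == "cuboidal") return("primary")
    "primary"
  }, character(1))
}

#' Tally follicle stages
#'
#' Counts classified stages over the non-excluded records; the excluded
#' count is reported separately so that counts conserve the input size.
#'
#' @param records `data.frame` of follicle records; if it has a `stage`
#'   column that is used, otherwise records are staged with
#'   [classify_follicle()].
#' @return List: `counts` (named vector over primordial/primary/secondary/
#'   antral), `excluded`, `n`.
#' @export
tally_stages <- function(records) {
  stages <- c("primordial", "primary", "secondary", "antral")
  if (!nrow(records)) {
    return(list(counts = stats::setNames(rep(0L, 4L), stages), excluded = 0L, n = 0L))
  }
  lab <- if ("stage" %in% names(records)) records$stage else classify_follicle(records)
  counts <- vapply(stages, function(s) sum(lab == s), integer(1))
  list(counts = counts, excluded = sum(lab == "excluded"), n = nrow(records))
}

#' Derive follicle counts from MVH/ZP3 immunofluorescence
#'
#' MVH (DDX4) marks every oocyte, so MVH-positive counts proxy the total
#' follicle number; ZP3 marks the zona pellucida of growing (non-primordial)
#' follicles. The MVH - ZP3 difference is therefore a follicle count whose
#' biological label is a policy choice: `"paper_literal"` labels it
#' `primary` (the convention used when growing follicles in neonatal
#' culture are essentially all primary), `"zp3_semantics"` labels it
#' `primordial` (ZP3-negative = not yet growing). A negative difference is
#' inconsistent and is reported as 0 with a warning.
#'
#' @param mvh_positive,zp3_positive Non-negative counts.
#' @param label_policy `"paper_literal"` or `"zp3_semantics"`.
#' @return List: `total`, `growing`, `difference`, `difference_label`,
#'   `warnings` (character vector).
#' @export
derive_if_counts <- function(mvh_positive, zp3_positive,
                             label_policy = c("paper_literal", "zp3_semantics")) {
  label_policy <- match.arg(label_policy)
  if (mvh_positive < 0 || zp3_positive < 0) {
    stop("derive_if_counts: counts must be >= 0", call. = FALSE)
  }
  warn <- character()
  diff <- mvh_positive - zp3_positive
  if (diff < 0) {
    warn <- c(warn, sprintf("ZP3-positive count (%d) exceeds MVH-positive count (%d); difference reported as 0",
                            zp3_positive, mvh_positive))
    warning(warn[length(warn)])
    diff <- 0
  }
  list(total = mvh_positive, growing = zp3_positive, difference = diff,
       difference_label = switch(label_policy,
                                 paper_literal = "primary",
                                 zp3_semantics = "primordial"),
       warnings = warn)
}

# antral diameter classes: SF < 250; F1 250-300; F2 (300, 350]; F3 (350, 400];
# F4 > 400 um. Printed integer class bounds (301-350, 351-400) are made
# half-open so every real-valued diameter receives exactly one class.
.diameter_class <- function(d) {
  if (d < 250) "SF"
  else if (d <= 300) "F1"
  else if (d <= 350) "F2"
  else if (d <= 400) "F3"
  else "F4"
}

.pub_score_map <- c(SF = -5L, F1 = -4L, F2 = -3L, F3 = -2L, F4 = -1L)

#' Puberty score from antral follicle diameters
#'
#' Measures peripubertal ovarian maturation from H&E sections: the six
#' largest healthy antral follicles are taken and the diameter class of the
#' single largest determines the score. Classes: SF < 250 um (score -5),
#' F1 250-300 um (-4), F2 300-350 um (-3), F3 350-400 um (-2), F4 > 400 um
#' (-1); upper bounds inclusive. Higher scores mean the ovary is closer to
#' ovulatory competence. With no healthy antral follicle the ovary scores
#' -5 (baseline) with flag `no_antral`.
#'
#' @param records `data.frame` of follicle records (columns
#'   `follicle_diameter`, `healthy`, plus either a `stage` column or the
#'   morphology columns read by [classify_follicle()]).
#' @return Object of class `puberty_score_result`: `six_largest`,
#'   `top_class`, `score`, `n_antral`, `flags`.
#' @export
puberty_score <- function(records) {
  stopifnot(is.data.frame(records))
  flags <- character()
  if (nrow(records)) {
    lab <- if ("stage" %in% names(records)) records$stage else classify_follicle(records)
    sel <- records[lab == "antral" & records$healthy %in% TRUE, , drop = FALSE]
  } else {
    sel <- records
  }
  if (nrow(sel)) {
    d <- sel$follicle_diameter
    bad <- is.na(d) | d <= 0
    if (any(bad)) {
      stop(sprintf("puberty_score: non-positive or missing diameter for record(s) %s",
                   paste(sel$id[bad], collapse = ", ")), call. = FALSE)
    }
  }
  if (!nrow(sel)) {
    flags <- c(flags, "no_antral")
    out <- list(six_largest = numeric(), top_class = "SF",
                score = .pub_score_map[["SF"]], n_antral = 0L, flags = flags)
    class(out) <- "puberty_score_result"
    return(out)
  }
  d <- sort(sel$follicle_diameter, decreasing = TRUE)
  if (length(d) < 6L) {
    flags <- c(flags, sprintf("only %d healthy antral follicle(s); fewer than the six measured by convention",
                              length(d)))
    warning(flags[length(flags)])
  }
  six <- utils::head(d, 6L)
  top_class <- .diameter_class(six[1])
  out <- list(six_largest = six, top_class = top_class,
              score = .pub_score_map[[top_class]],
              n_antral = length(d), flags = flags)
  class(out) <- "puberty_score_result"
  out
}

#' @export
print.puberty_score_result <- function(x, ...) {
  cat(sprintf("<puberty_score_result> top class %s, Pub-score %d (largest %s um; %d healthy antral)\n",
              x$top_class, x$score,
              if (length(x$six_largest)) format(x$six_largest[1]) else "none",
              x$n_antral))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
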