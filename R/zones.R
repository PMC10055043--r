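#' Zone labels for olfactory receptor identity
#'
#' The main olfactory epithelium (MOE) is divided into five dorsoventral
#' bands ("zones"); zone 1 is dorsal-most, zone 5 ventral-most.  Class I
#' (fish-like) ORs are expressed in zone 1 but regulated separately, so they
#' are carried as their own category.  Labels are represented as a factor
#' with levels \code{classI, 1, 2, 3, 4, 5, unknown}.
#'
#' @return Character vector of the canonical level set.
#' @export
zone_levels <- function() c("classI", "1", "2", "3", "4", "5", "unknown")

#' @rdname zone_levels
#' @param x character/factor/numeric vector of zone labels
#' @return \code{zone_factor}: `x` coerced to a factor on the canonical levels.
#' @export
zone_factor <- function(x) {
  x <- as.character(x)
  bad <- !(is.na(x) | x %in% zone_levels())
  if (any(bad)) {
    stop("invalid zone label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  x[is.na(x)] <- "unknown"
  factor(x, levels = zone_levels())
}

#' Numeric zone of a label
#'
#' Ordering is defined on zones 1..5 only; \code{classI} compares as
#' dorsal-most (it is mapped to 1 when \code{classI_as = 1}) and
#' \code{unknown} maps to NA.
#'
#' @param zone zone labels (factor or character)
#' @param classI_as numeric value used for class I (default \code{NA};
#'   pass \code{1} to treat class I as dorsal-most)
#' @return numeric vector in 1..5 or NA
#' @export
zone_number <- function(zone, classI_as = NA_real_) {
  z <- as.character(zone)
  out <- suppressWarnings(as.numeric(z))
  out[z == "classI"] <- classI_as
  out
}

#' Discretize a continuous zone index into a zone label
#'
#' Continuous per-gene zone indices (real values in \[1, 5\]) are binned by
#' rounding to the nearest integer; exact half-way ties (x.5) round towards
#' the more ventral zone (round half up) by default.  The class I flag
#' dominates: class I ORs get the \code{classI} label regardless of index.
#' Missing indices give \code{unknown}.
#'
#' @param zone_index numeric vector of continuous indices in \[0.5, 5.5)
#' @param is_class_I logical vector (recycled)
#' @param gene_id optional gene ids used in error messages
#' @param tie either "up" (default, x.5 -> x+1) or "down"
#' @return factor of zone labels (see [zone_levels()])
#' @examples
#' assign_zone(c(2.4, 2.5, 1.0), c(FALSE, FALSE, FALSE))
#' assign_zone(3.7, TRUE)   # classI dominates
#' @export
assign_zone <- function(zone_index, is_class_I = FALSE, gene_id = NULL,
                        tie = c("up", "down")) {
  tie <- match.arg(tie)
  n <- max(length(zone_index), length(is_class_I))
  zone_index <- rep_len(as.numeric(zone_index), n)
  is_class_I <- rep_len(as.logical(is_class_I), n)
  oob <- !is.na(zone_index) & !is_class_I &
    (zone_index < 0.5 | zone_index >= 5.5)
  if (any(oob)) {
    who <- if (is.null(gene_id)) paste0("#", which(oob)) else
      rep_len(as.character(gene_id), n)[oob]
    stop("zone_index outside [0.5, 5.5) for gene(s): ",
         paste(unique(who), collapse = ", "))
  }
  z <- if (tie == "up") floor(zone_index + 0.5) else ceiling(zone_index - 0.5)
  lab <- as.character(z)
  lab[is.na(zone_index)] <- "unknown"
  lab[is_class_I] <- "classI"
  zone_factor(lab)
}

# Dorsal-first ordering used for deterministic tie-breaks: classI counts as
# dorsal-most, then zones 1..5; unknown sorts last.
zone_rank <- function(zone) {
  r <- match(as.character(zone), c("classI", "1", "2", "3", "4", "5"))
  r[is.na(r)] <- 7L
  r
}
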