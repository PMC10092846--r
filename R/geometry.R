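#' Volume of half a spheroid
#'
#' Open cup nests are approximated as half a spheroid: a dome with
#' circular cross-section of diameter \code{mean_diameter} and height
#' \code{mean_height}. Both the whole nest and the inner cup are treated
#' this way; the outer (wall) volume is their difference.
#'
#' @param mean_diameter Diameter across the rim, cm (mean of up to four
#'   measurements around the circumference).
#' @param mean_height Height of the dome, cm (mean of up to two
#'   measurements).
#' @return Volume in cm^3: \eqn{(2/3) \pi (d/2)^2 h}. Vectorised.
#' @examples
#' half_spheroid_volume(10, 6) # 100 * pi
#' @export
half_spheroid_volume <- function(mean_diameter, mean_height) {
  if (any(mean_diameter < 0, na.rm = TRUE) || any(mean_height < 0, na.rm = TRUE))
    stop("invalid dimension: diameters and heights must be non-negative")
  (2 / 3) * pi * (mean_diameter / 2)^2 * mean_height
}

#' Construct a set of nest dimensions
#'
#' Bundles raw linear measurements of one nest record. Up to four
#' diameters and two heights are accepted for each of the outer shell and
#' the inner cup; records with fewer replicates (common in literature
#' sources) are kept and averaged as-is.
#'
#' @param outer_diameters,inner_diameters Numeric vectors, cm (length 1-4).
#' @param outer_heights,inner_heights Numeric vectors, cm (length 1-2).
#' @return An object of class \code{"nest_dimensions"} with elements
#'   \code{outer_diameters}, \code{outer_heights}, \code{inner_diameters},
#'   \code{inner_heights} and computed means \code{D}, \code{H}, \code{d},
#'   \code{h} (\code{NA} where a side was not measured).
#' @export
nest_dimensions <- function(outer_diameters = NULL, outer_heights = NULL,
                            inner_diameters = NULL, inner_heights = NULL) {
  chk <- function(x, nmax, what) {
    if (is.null(x) || length(x) == 0L) return(NULL)
    x <- as.numeric(x[!is.na(x)])
    if (length(x) == 0L) return(NULL)
    if (length(x) > nmax)
      stop("too many ", what, " values (max ", nmax, ")")
    if (any(x <= 0))
      stop("invalid dimension: non-positive ", what)
    x
  }
  out <- list(
    outer_diameters = chk(outer_diameters, 4L, "outer diameter"),
    outer_heights   = chk(outer_heights, 2L, "outer height"),
    inner_diameters = chk(inner_diameters, 4L, "inner diameter"),
    inner_heights   = chk(inner_heights, 2L, "inner height")
  )
  mn <- function(x) if (is.null(x)) NA_real_ else mean(x)
  out$D <- mn(out$outer_diameters); out$H <- mn(out$outer_heights)
  out$d <- mn(out$inner_diameters); out$h <- mn(out$inner_heights)
  # small (<=0.5%) crossings of the inner/outer means are tolerated here
  # and resolved by the volume clamp in nest_volumes()
  if (!is.na(out$D) && !is.na(out$d) && out$d > out$D * 1.005)
    stop("invalid dimensions: mean inner diameter exceeds mean outer diameter")
  if (!is.na(out$H) && !is.na(out$h) && out$h > out$H * 1.005)
    stop("invalid dimensions: mean inner height exceeds mean outer height")
  structure(out, class = "nest_dimensions")
}

#' Nest volumes from raw dimensions
#'
#' Computes full, inner and outer volumes for one measurement record.
#' The full nest and the inner cup are each modelled as half a spheroid
#' on the mean of the available replicate measurements; the outer volume
#' is the full volume minus the inner cup volume and proxies the amount
#' of nest material. Records measured only internally (e.g. misshapen or
#' cavity-constrained specimens) yield an inner volume with full and
#' outer volumes absent.
#'
#' Inner volumes exceeding the full volume by at most 0.5\% (digitisation
#' noise) are clamped to equality; larger violations are an error.
#'
#' @param dims A \code{\link{nest_dimensions}} object.
#' @return List of class \code{"nest_volumes"}: \code{full_volume},
#'   \code{inner_volume}, \code{outer_volume} (cm^3, \code{NA} where the
#'   required dimensions were absent).
#' @export
nest_volumes <- function(dims) {
  stopifnot(inherits(dims, "nest_dimensions"))
  has_outer <- !is.na(dims$D) && !is.na(dims$H)
  has_inner <- !is.na(dims$d) && !is.na(dims$h)
  if (!has_outer && !has_inner)
    stop("need at least the inner (d, h) or outer (D, H) dimension pair")
  full  <- if (has_outer) half_spheroid_volume(dims$D, dims$H) else NA_real_
  inner <- if (has_inner) half_spheroid_volume(dims$d, dims$h) else NA_real_
  outer <- NA_real_
  if (has_outer && has_inner) {
    if (inner > full) {
      if (inner <= full * 1.005) {
        inner <- full
      } else {
        stop("inconsistent volumes: inner cup volume exceeds full nest volume by >0.5%")
      }
    }
    outer <- full - inner
  }
  structure(list(full_volume = full, inner_volume = inner,
                 outer_volume = outer), class = "nest_volumes")
}

#' Interpret a literature dimension tuple
#'
#' Handbook nest descriptions report dimensions in loose conventions.
#' This applies the fixed interpretation rules used at data entry: values
#' separated by "by" or a multiplication sign are nest length and width
#' (diameters D1 and D3); a third such value is nest height; unqualified
#' values refer to the external portion of the nest; an unqualified
#' "depth" is the external height, unless it directly follows a
#' description of the inner cup diameter, in which case it is the inner
#' height.
#'
#' @param values Numeric vector of 1-3 positive lengths (cm).
#' @param separator_style \code{"by_or_x"} for length-by-width style
#'   tuples, \code{"plain"} for a single depth/height value.
#' @param qualifier \code{"none"}, \code{"internal"} or \code{"external"}.
#' @param preceded_by_inner_diameter Logical; was the value directly
#'   preceded by an inner-cup diameter description?
#' @return A named list fragment of a \code{\link{nest_dimensions}}:
#'   some of \code{D1}, \code{D3}, \code{H}, \code{d1}, \code{d3},
#'   \code{h}.
#' @export
interpret_dimension_tuple <- function(values,
                                      separator_style = c("by_or_x", "plain"),
                                      qualifier = c("none", "internal", "external"),
                                      preceded_by_inner_diameter = FALSE) {
  separator_style <- match.arg(separator_style)
  qualifier <- match.arg(qualifier)
  values <- as.numeric(values)
  if (length(values) < 1L || length(values) > 3L)
    stop("ambiguous tuple: expected 1-3 values, got ", length(values))
  if (any(!is.finite(values)) || any(values <= 0))
    stop("invalid dimension: values must be positive")
  # unqualified measurements refer to the external portion of the nest
  internal <- qualifier == "internal"
  frag <- list()
  if (separator_style == "by_or_x") {
    if (length(values) >= 2L) {
      if (internal) {
        frag$d1 <- values[1L]; frag$d3 <- values[2L]
      } else {
        frag$D1 <- values[1L]; frag$D3 <- values[2L]
      }
      if (length(values) == 3L) {
        if (internal) frag$h <- values[3L] else frag$H <- values[3L]
      }
    } else {
      if (internal) frag$d1 <- values[1L] else frag$D1 <- values[1L]
    }
  } else {
    if (length(values) != 1L)
      stop("ambiguous tuple: plain style takes a single depth value")
    # "depth" with no qualifier is external height unless directly
    # preceded by an inner cup diameter description
    if (internal || (qualifier == "none" && preceded_by_inner_diameter)) {
      frag$h <- values[1L]
    } else {
      frag$H <- values[1L]
    }
  }
  frag
}

# ---- measurement table I/O ---------------------------------------------

.dim_cols <- c(paste0("D", 1:4), paste0("H", 1:2),
               paste0("d", 1:4), paste0("h", 1:2))

#' Read a nest measurement table
#'
#' One row per measurement record. Expected columns (renameable through
#' \code{col_map}): \code{species_id}, \code{source} ("museum" or
#' "literature"), optional \code{site_label}, and dimension columns
#' \code{D1..D4}, \code{H1..H2} (outer), \code{d1..d4}, \code{h1..h2}
#' (inner), in cm. Missing replicates are left \code{NA}.
#'
#' @param path CSV or TSV file (separator sniffed from the extension).
#' @param col_map Optional named character vector mapping file column
#'   names to the canonical names, e.g. \code{c(taxon = "species_id")}.
#' @param units \code{"cm"} (default) or \code{"mm"}; mm values are
#'   converted to cm at ingest so all downstream geometry is in cm.
#' @return A \code{data.frame} of measurement records.
#' @export
read_measurements <- function(path, col_map = NULL, units = c("cm", "mm")) {
  units <- match.arg(units)
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    idx <- match(names(col_map), names(df))
    if (anyNA(idx)) stop("col_map names absent from file: ",
                         paste(names(col_map)[is.na(idx)], collapse = ", "))
    names(df)[idx] <- unname(col_map)
  }
  if (!all(c("species_id", "source") %in% names(df)))
    stop("measurement table needs 'species_id' and 'source' columns")
  if (!all(df$source %in% c("museum", "literature")))
    stop("source must be 'museum' or 'literature'")
  if (any(!nzchar(df$species_id)) || anyNA(df$species_id))
    stop("species_id must be non-empty")
  if (!"site_label" %in% names(df)) df$site_label <- ""
  present <- intersect(.dim_cols, names(df))
  if (units == "mm") df[present] <- df[present] / 10
  df
}

#' Append half-spheroid volume columns to a measurement table
#'
#' @param df Measurement table as returned by
#'   \code{\link{read_measurements}} (or the synthetic generator).
#' @return The table with \code{full_volume}, \code{inner_volume} and
#'   \code{outer_volume} columns (cm^3) appended.
#' @export
add_volumes <- function(df) {
  pick <- function(row, cols) {
    v <- unlist(row[intersect(cols, names(row))], use.names = FALSE)
    v[!is.na(v)]
  }
  vols <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    dims <- nest_dimensions(
      outer_diameters = pick(row, paste0("D", 1:4)),
      outer_heights   = pick(row, paste0("H", 1:2)),
      inner_diameters = pick(row, paste0("d", 1:4)),
      inner_heights   = pick(row, paste0("h", 1:2)))
    v <- nest_volumes(dims)
    c(v$full_volume, v$inner_volume, v$outer_volume)
  })
  vols <- do.call(rbind, vols)
  df$full_volume <- vols[, 1]; df$inner_volume <- vols[, 2]
  df$outer_volume <- vols[, 3]
  df
}

#' Write a measurement table
#'
#' @param df Measurement table (with or without volume columns).
#' @param path Output CSV/TSV path; separator chosen from extension.
#' @export
write_measurements <- function(df, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
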