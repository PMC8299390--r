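# DNA substrate coordinate maps: parS sites, EcoRI roadblock footprints,
# handles. Coordinates are 0-based, half-open intervals in base pairs.

#' Names of the built-in DNA substrates
#'
#' @return Character vector of identifiers accepted by [build_substrate()].
#' @export
substrate_names <- function() {
  c("39x_parS", "ecoRI_39x_parS", "ecoRI_7x_parS", "2x_parS",
    "26x", "13x", "7x", "4x", "1x", "scrambled", "lambda_control",
    "tpm_1717")
}

#' Rise per base pair of B-form DNA (nm)
#' @export
RISE_NM_PER_BP <- 0.34

#' Convert base pairs to nanometres of DNA contour
#'
#' Uses the B-DNA rise of 0.34 nm per base pair by default, the conversion
#' used throughout for mapping genomic coordinates onto imaging coordinates.
#'
#' @param x Length in base pairs (non-negative).
#' @param rise Rise per base pair in nm.
#' @return Length in nm.
#' @export
bp_to_nm <- function(x, rise = RISE_NM_PER_BP) {
  stopifnot(is.numeric(x), all(x >= 0), rise > 0)
  x * rise
}

#' @rdname bp_to_nm
#' @export
nm_to_bp <- function(x, rise = RISE_NM_PER_BP) {
  stopifnot(is.numeric(x), all(x >= 0), rise > 0)
  x / rise
}

# one group of n parS palindromes, `spacing` bp between palindrome starts
.parS_group <- function(n, start, spacing, width) {
  starts <- start + spacing * (seq_len(n) - 1L)
  data.frame(start = starts, end = starts + width)
}

# lay out parS clusters; cluster_groups is a list of integer vectors, one
# vector of group sizes per cluster; returns sites plus the region end
.layout_parS <- function(region_start, cluster_groups, cluster_gap,
                         group_gap, spacing, width) {
  sites <- list()
  cur <- region_start
  g <- 0L
  for (ci in seq_along(cluster_groups)) {
    sizes <- cluster_groups[[ci]]
    for (gi in seq_along(sizes)) {
      g <- g + 1L
      grp <- .parS_group(sizes[gi], cur, spacing, width)
      grp$group <- g
      grp$cluster <- ci
      sites[[length(sites) + 1L]] <- grp
      cur <- max(grp$end) + group_gap
    }
    cur <- cur - group_gap
    if (ci < length(cluster_groups)) cur <- cur + cluster_gap
  }
  df <- do.call(rbind, sites)
  df$kind <- "parS"
  df
}

.new_substrate <- function(name, length, sites, rise = RISE_NM_PER_BP) {
  if (nrow(sites) > 0) {
    sites <- sites[order(sites$start), , drop = FALSE]
    rownames(sites) <- NULL
    parS <- sites$kind == "parS"
    if (any(parS)) {
      sites$label[parS] <- sprintf("parS_%02d", seq_len(sum(parS)))
    }
    rb <- sites$kind == "roadblock"
    if (any(rb)) sites$label[rb] <- sprintf("ecoRI_%d", seq_len(sum(rb)))
  }
  map <- structure(
    list(name = name, length = as.numeric(length), sites = sites,
         rise_per_bp = rise),
    class = "substrate_map")
  validate_substrate(map)
  map
}

.empty_sites <- function() {
  data.frame(start = numeric(0), end = numeric(0), group = integer(0),
             cluster = integer(0), kind = character(0), label = character(0))
}

#' Validate a substrate map
#'
#' Checks the interval invariants: positive total length, sites sorted by
#' start, non-overlapping, within `[0, length)`, and 16 bp parS footprints.
#'
#' @param map A `substrate_map`.
#' @return The map, invisibly; errors on violation.
#' @export
validate_substrate <- function(map) {
  stopifnot(inherits(map, "substrate_map"))
  if (map$length <= 0) stop("substrate length must be positive")
  s <- map$sites
  if (nrow(s) > 0) {
    if (any(s$start < 0) || any(s$end > map$length) || any(s$start >= s$end))
      stop("sites must satisfy 0 <= start < end <= length")
    if (is.unsorted(s$start)) stop("sites must be sorted by start")
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("sites must not overlap")
    if (any(s$kind == "parS" & (s$end - s$start) != 16))
      stop("parS footprint must be 16 bp")
  }
  invisible(map)
}

#' Build a named DNA substrate map
#'
#' Returns the coordinate map of one of the DNA constructs used in the
#' ParB single-molecule experiments: dual-trap (C-trap) substrates carrying
#' 39, 7 or 2 parS palindromes (optionally flanked by 5x EcoRI roadblock
#' groups), magnetic-tweezers substrates with 1-26 parS copies, the
#' scrambled-parS and lambda-DNA controls, and the 1717 bp
#' tethered-particle-motion substrate. All printed inter-feature distances
#' (1905 bp between the two parS clusters of the 39x construct; 3613 bp from
#' the last parS to the nearest EcoRI group on the EcoRI 39x construct) are
#' reproduced exactly. Unprinted spacings (within-group parS spacing, EcoRI
#' footprint) are configurable defaults, not measured values.
#'
#' @param name One of [substrate_names()].
#' @param group_gap Gap in bp between parS groups inside a cluster.
#' @param site_spacing Spacing in bp between parS palindrome starts in a group.
#' @param parS_width parS palindrome footprint, bp (16).
#' @param ecoRI_footprint Merged footprint of a 5x EcoRI group, bp.
#' @return A `substrate_map`: list with `name`, `length` (bp), `sites`
#'   (data frame with `label`, `start`, `end`, `kind`, `group`, `cluster`)
#'   and `rise_per_bp`.
#' @examples
#' m <- build_substrate("39x_parS")
#' sum(m$sites$kind == "parS")  # 39
#' @export
build_substrate <- function(name, group_gap = 300, site_spacing = 50,
                            parS_width = 16, ecoRI_footprint = 60) {
  valid <- substrate_names()
  if (!is.character(name) || length(name) != 1 || !(name %in% valid)) {
    stop("unknown substrate '", paste(name, collapse = ","),
         "'; valid identifiers: ", paste(valid, collapse = ", "))
  }
  lay <- function(start, clusters, cluster_gap = 1905) {
    .layout_parS(start, clusters, cluster_gap, group_gap, site_spacing,
                 parS_width)
  }
  rb <- function(start) {
    data.frame(start = start, end = start + ecoRI_footprint,
               group = NA_integer_, cluster = NA_integer_,
               kind = "roadblock")
  }
  # 39x arrangement: two clusters 1905 bp apart; the smaller holds two
  # groups (6+7 sites), the larger four groups (6+7+6+7).
  cl39 <- list(c(6L, 7L), c(6L, 7L, 6L, 7L))
  sites <- switch(
    name,
    "39x_parS" = lay(7000, cl39),
    "ecoRI_39x_parS" = {
      p <- lay(7460, cl39)
      # downstream EcoRI group sits 3613 bp beyond the last parS; the
      # upstream group leaves a ~5 kbp protected outer segment, the
      # downstream one a ~1 kbp segment.
      rbind(rb(5000), p, rb(max(p$end) + 3613))
    },
    "ecoRI_7x_parS" = {
      p <- lay(5560, list(7L))
      rbind(rb(5000), p, rb(max(p$end) + 1500))
    },
    "2x_parS" = lay(3967, list(2L)),
    "26x" = lay(2968, list(c(6L, 7L, 6L, 7L))),
    "13x" = lay(3559, list(c(6L, 7L))),
    "7x"  = lay(3842, list(7L)),
    "4x"  = lay(3917, list(4L)),
    "1x"  = lay(3992, list(1L)),
    "scrambled" = NULL,
    "lambda_control" = NULL,
    "tpm_1717" = lay(850, list(1L))
  )
  if (is.null(sites)) {
    sites <- .empty_sites()
  } else {
    sites$label <- NA_character_
    sites <- sites[, c("start", "end", "group", "cluster", "kind", "label")]
  }
  len <- switch(name,
                "39x_parS" = 20000, "ecoRI_39x_parS" = 16984,
                "ecoRI_7x_parS" = 12000, "2x_parS" = 8000,
                "26x" = 8000, "13x" = 8000, "7x" = 8000, "4x" = 8000,
                "1x" = 8000, "scrambled" = 8000,
                "lambda_control" = 48502, "tpm_1717" = 1717)
  .new_substrate(name, len, sites)
}

# resolve a selector to a (start, end) pair; boundaries collapse to a point
.resolve_selector <- function(map, sel) {
  s <- map$sites
  hit <- which(s$label == sel)
  if (length(hit) == 1) {
    return(c(start = s$start[hit], end = s$end[hit]))
  }
  if (length(hit) > 1) stop("selector '", sel, "' matches ", length(hit),
                            " sites")
  parS <- s[s$kind == "parS", , drop = FALSE]
  pt <- function(x) c(start = x, end = x)
  if (sel == "first_parS" && nrow(parS) > 0) {
    r <- parS[1, ]; return(c(start = r$start, end = r$end))
  }
  if (sel == "last_parS" && nrow(parS) > 0) {
    r <- parS[nrow(parS), ]; return(c(start = r$start, end = r$end))
  }
  m <- regmatches(sel, regexec("^cluster([0-9]+)_(start|end)$", sel))[[1]]
  if (length(m) == 3) {
    sub <- parS[!is.na(parS$cluster) & parS$cluster == as.integer(m[2]), ,
                drop = FALSE]
    if (nrow(sub) == 0) stop("selector '", sel, "' matches 0 sites")
    return(if (m[3] == "start") pt(min(sub$start)) else pt(max(sub$end)))
  }
  m <- regmatches(sel, regexec("^group([0-9]+)_(start|end)$", sel))[[1]]
  if (length(m) == 3) {
    sub <- parS[!is.na(parS$group) & parS$group == as.integer(m[2]), ,
                drop = FALSE]
    if (nrow(sub) == 0) stop("selector '", sel, "' matches 0 sites")
    return(if (m[3] == "start") pt(min(sub$start)) else pt(max(sub$end)))
  }
  stop("selector '", sel, "' matches 0 sites; use a site label, ",
       "first_parS/last_parS, clusterK_start/end or groupK_start/end")
}

#' Distance in bp between two features of a substrate
#'
#' Selectors may be site labels (`"parS_01"`, `"ecoRI_2"`), `"first_parS"`,
#' `"last_parS"`, or cluster/group boundaries (`"cluster1_end"`,
#' `"group3_start"`). The distance is the gap `start(downstream) -
#' end(upstream)` and is symmetric in its arguments; a selector compared
#' with itself gives 0.
#'
#' @param map A `substrate_map`.
#' @param a,b Selectors.
#' @return Distance in bp.
#' @examples
#' feature_distance(build_substrate("39x_parS"), "cluster1_end",
#'                  "cluster2_start")  # 1905
#' @export
feature_distance <- function(map, a, b) {
  ra <- .resolve_selector(map, a)
  rb <- .resolve_selector(map, b)
  if (identical(unname(ra), unname(rb))) return(0)
  if (ra[["start"]] <= rb[["start"]]) {
    up <- ra; down <- rb
  } else {
    up <- rb; down <- ra
  }
  unname(down[["start"]] - up[["end"]])
}

#' Head-to-head tandem (double-length) version of a substrate
#'
#' Models the tandem tethers formed when two copies of the construct ligate
#' head-to-head: the map length doubles and the second half mirrors the
#' first about the junction, so the site count doubles and the pattern is
#' palindromic about the midpoint.
#'
#' @param map A `substrate_map`.
#' @return A new `substrate_map` of twice the length.
#' @export
make_tandem <- function(map) {
  stopifnot(inherits(map, "substrate_map"))
  L <- map$length
  s <- map$sites
  if (nrow(s) > 0) {
    mirror <- s
    mirror$start <- 2 * L - s$end
    mirror$end <- 2 * L - s$start
    maxc <- suppressWarnings(max(s$cluster, na.rm = TRUE))
    if (is.finite(maxc)) {
      mirror$cluster <- ifelse(is.na(s$cluster), NA_integer_,
                               2L * maxc - s$cluster + 1L)
    }
    maxg <- suppressWarnings(max(s$group, na.rm = TRUE))
    if (is.finite(maxg)) {
      mirror$group <- ifelse(is.na(s$group), NA_integer_,
                             2L * maxg - s$group + 1L)
    }
    s <- rbind(s, mirror)
  }
  .new_substrate(paste0("tandem_", map$name), 2 * L, s, map$rise_per_bp)
}

# internal: featureless substrate of a given length (used by clamp-only
# simulations on e.g. lambda-length DNA)
.bare_substrate <- function(length_bp, name = "bare") {
  .new_substrate(name, length_bp, .empty_sites())
}

#' @export
print.substrate_map <- function(x, ...) {
  n_parS <- sum(x$sites$kind == "parS")
  n_rb <- sum(x$sites$kind == "roadblock")
  cat(sprintf(
    "<substrate_map> %s: %g bp (%.2f um contour), %d parS, %d roadblock(s)\n",
    x$name, x$length, x$length * x$rise_per_bp / 1000, n_parS, n_rb))
  invisible(x)
}

#' Write / read a substrate map as BED-like tab-separated text
#'
#' One `#` header line carries the name, total length and rise; the body is
#' a four-plus-column BED-like table (`label`, `start`, `end`, `kind`, plus
#' `group` and `cluster` annotations). The round trip is lossless.
#'
#' @param map A `substrate_map`.
#' @param path File path.
#' @return `write_substrate` returns `path` invisibly; `read_substrate`
#'   returns a `substrate_map`.
#' @export
write_substrate <- function(map, path) {
  stopifnot(inherits(map, "substrate_map"))
  hdr <- sprintf("#parbslide-substrate\tname=%s\tlength=%g\trise_per_bp=%g",
                 map$name, map$length, map$rise_per_bp)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  s <- map$sites
  df <- data.frame(label = s$label, start = s$start, end = s$end,
                   kind = s$kind, group = s$group, cluster = s$cluster)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_substrate
#' @export
read_substrate <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "#parbslide-substrate"))
    stop("line 1: expected '#parbslide-substrate' header in ", path)
  kv <- strsplit(strsplit(hdr, "\t")[[1]][-1], "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          stringsAsFactors = FALSE,
                          colClasses = c(label = "character",
                                         start = "numeric", end = "numeric",
                                         kind = "character",
                                         group = "integer",
                                         cluster = "integer"))
  sites <- data.frame(start = as.numeric(df$start), end = as.numeric(df$end),
                      group = as.integer(df$group),
                      cluster = as.integer(df$cluster),
                      kind = df$kind, label = df$label)
  .new_substrate(vals[["name"]], as.numeric(vals[["length"]]), sites,
                 as.numeric(vals[["rise_per_bp"]]))
}

#' Export a substrate map as GFF3
#'
#' Writes a GFF3 file (1-based inclusive coordinates, per the format) with
#' one `protein_binding_site` feature per parS palindrome or roadblock
#' footprint.
#'
#' @param map A `substrate_map`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
export_substrate_gff3 <- function(map, path) {
  stopifnot(inherits(map, "substrate_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %g", map$name, map$length), con)
  s <- map$sites
  if (nrow(s) > 0) {
    lines <- sprintf(
      "%s\tparbslide\tprotein_binding_site\t%g\t%g\t.\t.\t.\tID=%s;Name=%s;kind=%s",
      map$name, s$start + 1, s$end, s$label, s$label, s$kind)
    writeLines(lines, con)
  }
  invisible(path)
}
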