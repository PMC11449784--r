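#' Default rendering style
#'
#' Styling knobs for [render_svg()]: canvas size, glyph geometry, colors and
#' edge styling. The node-shape semantics are fixed (circle = gene,
#' ellipse = metabolite, small gray dot = connector); everything else is
#' configurable here or via a YAML file with the same field names
#' ([read_style()]).
#'
#' @return named list of style settings.
#' @export
default_style <- function() {
  list(width = 800, height = 600, margin = 60,
       glyph_radius = 14, ellipse_aspect_x = 1.35, ellipse_aspect_y = 0.8,
       dot_radius = 3, gray = GRAY_HEX,
       edge_color = "#999999", edge_width = 1,
       stroke = "#333333", stroke_width = 0.6,
       label_size = 8, background = "#FFFFFF")
}

#' @rdname default_style
#' @param path YAML file with style overrides.
#' @export
read_style <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML styles requires the `yaml` package", call. = FALSE)
  }
  utils::modifyList(default_style(), yaml::read_yaml(path))
}

#' Pie glyph for a network vertex
#'
#' Encodes a vertex's five-comparison fold-change vector as a pie with five
#' equal 72-degree sectors. The first sector is centered on 12 o'clock
#' (spanning -36 to +36 degrees) and sectors proceed clockwise in comparison
#' order; empty or non-significant slots are gray. Genes are drawn as
#' circles, metabolites as ellipses, connectors as small gray dots with no
#' sectors.
#'
#' @param colors character vector of 5 sector fill colors (`NA` renders
#'   gray), or `NULL` for a connector.
#' @param shape `"circle"`, `"ellipse"` or `"dot"`.
#' @param gray fill used for empty slots.
#' @return a `pie_glyph`: list with `shape` and a `sectors` data frame
#'   (`start`, `end` in degrees clockwise from 12 o'clock, `fill`).
#' @export
pie_glyph <- function(colors, shape = c("circle", "ellipse", "dot"),
                      gray = GRAY_HEX) {
  shape <- match.arg(shape)
  if (shape == "dot") {
    return(structure(list(shape = "dot",
                          sectors = data.frame(start = numeric(),
                                               end = numeric(),
                                               fill = character())),
                     class = "pie_glyph"))
  }
  stopifnot(length(colors) == N_COMPARISONS)
  colors[is.na(colors)] <- gray
  start <- -36 + 72 * (seq_len(N_COMPARISONS) - 1L)
  structure(list(shape = shape,
                 sectors = data.frame(start = start, end = start + 72,
                                      fill = colors,
                                      stringsAsFactors = FALSE)),
            class = "pie_glyph")
}

glyph_for_vertex <- function(network, i, gray = GRAY_HEX) {
  kind <- network$vertices$vkind[i]
  shape <- switch(kind, gene = "circle", metabolite = "ellipse",
                  connector = "dot")
  cols <- if (kind == "connector") NULL else network$color[i, ]
  pie_glyph(cols, shape, gray = gray)
}

#' Load or compute 2D vertex coordinates
#'
#' `load_layout()` reads a TSV with columns `vertex`, `x`, `y` and (when a
#' network is supplied) checks that every vertex has a coordinate.
#' `compute_layout()` is the seeded fallback: a force-directed
#' (Fruchterman-Reingold) layout, deterministic per seed.
#'
#' @param path layout TSV path.
#' @param network an `integrative_network`.
#' @param seed integer seed for the force-directed fallback.
#' @return data frame with columns `vertex`, `x`, `y`.
#' @export
load_layout <- function(path, network = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("vertex", "x", "y") %in% colnames(df))) {
    stop("layout TSV needs columns vertex, x, y", call. = FALSE)
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    stop("layout coordinates must be finite", call. = FALSE)
  }
  if (!is.null(network)) {
    missing <- setdiff(network$vertices$id, df$vertex)
    if (length(missing)) {
      stop(sprintf("layout is missing coordinate(s) for vertex: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  df[, c("vertex", "x", "y")]
}

#' @rdname load_layout
#' @export
compute_layout <- function(network, seed = 1) {
  stopifnot(inherits(network, "integrative_network"))
  if (!nrow(network$vertices)) {
    return(data.frame(vertex = character(), x = numeric(), y = numeric()))
  }
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = FALSE,
    vertices = network$vertices$id)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  data.frame(vertex = network$vertices$id, x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}

#' @rdname load_layout
#' @param layout a layout data frame.
#' @export
write_layout_tsv <- function(layout, path) {
  utils::write.table(layout, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# point on the glyph outline at `deg` degrees clockwise from 12 o'clock
arc_point <- function(cx, cy, rx, ry, deg) {
  rad <- deg * pi / 180
  c(x = cx + rx * sin(rad), y = cy - ry * cos(rad))
}

sector_path <- function(cx, cy, rx, ry, start, end, fill, stroke,
                        stroke_width) {
  p1 <- arc_point(cx, cy, rx, ry, start)
  p2 <- arc_point(cx, cy, rx, ry, end)
  sprintf(paste0('<path d="M %.3f %.3f L %.3f %.3f A %.3f %.3f 0 0 1 ',
                 '%.3f %.3f Z" fill="%s" stroke="%s" stroke-width="%.2f"/>'),
          cx, cy, p1[["x"]], p1[["y"]], rx, ry, p2[["x"]], p2[["y"]],
          fill, stroke, stroke_width)
}

#' Render an integrative network as SVG
#'
#' Draws one pie glyph per vertex at its layout coordinates (circles for
#' genes, ellipses for metabolites, small gray dots for connectors; five
#' 72-degree sectors colored by the per-comparison fold-change colors), one
#' line per edge with an arrowhead on directed edges, and a blue-white-red
#' color-scale legend. Output is deterministic: identical inputs yield
#' byte-identical SVG.
#'
#' @param network an `integrative_network`.
#' @param layout layout data frame (`vertex`, `x`, `y`) covering all
#'   vertices; defaults to [compute_layout()].
#' @param style style list, see [default_style()].
#' @param path optional output file.
#' @return the SVG document as a single string, invisibly when `path` is
#'   given.
#' @export
render_svg <- function(network, layout = NULL, style = default_style(),
                       path = NULL) {
  stopifnot(inherits(network, "integrative_network"))
  if (anyDuplicated(network$vertices$id)) {
    stop(sprintf("duplicate vertex id(s): %s",
                 paste(unique(network$vertices$id[
                   duplicated(network$vertices$id)]), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(layout)) layout <- compute_layout(network)
  missing <- setdiff(network$vertices$id, layout$vertex)
  if (length(missing)) {
    stop(sprintf("layout is missing coordinate(s) for vertex: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  s <- style
  # map layout coordinates onto the canvas, preserving aspect per axis
  xy <- layout[match(network$vertices$id, layout$vertex), , drop = FALSE]
  rescale <- function(v, lo, hi) {
    if (nrow(xy) == 0L) return(numeric())
    rng <- range(v)
    if (diff(rng) < .Machine$double.eps) {
      rep((lo + hi) / 2, length(v))
    } else {
      lo + (v - rng[1]) / diff(rng) * (hi - lo)
    }
  }
  px <- rescale(xy$x, s$margin, s$width - s$margin)
  py <- rescale(xy$y, s$margin, s$height - s$margin)
  pos <- stats::setNames(seq_along(px), network$vertices$id)

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            s$width, s$height, s$width, s$height),
    "<defs>",
    sprintf(paste0('<marker id="arrow" viewBox="0 0 10 10" refX="9" ',
                   'refY="5" markerWidth="6" markerHeight="6" ',
                   'orient="auto-start-reverse">',
                   '<path d="M 0 0 L 10 5 L 0 10 z" fill="%s"/></marker>'),
            s$edge_color),
    '<linearGradient id="fcscale" x1="0" y1="0" x2="1" y2="0">',
    '<stop offset="0" stop-color="#0000FF"/>',
    '<stop offset="0.5" stop-color="#FFFFFF"/>',
    '<stop offset="1" stop-color="#FF0000"/>',
    "</linearGradient>",
    "</defs>",
    sprintf('<rect width="%d" height="%d" fill="%s"/>',
            s$width, s$height, s$background)
  )

  e <- network$edges
  edge_lines <- character(nrow(e))
  for (i in seq_len(nrow(e))) {
    i1 <- pos[[e$from[i]]]
    i2 <- pos[[e$to[i]]]
    marker <- if (e$directed[i]) ' marker-end="url(#arrow)"' else ""
    edge_lines[i] <- sprintf(
      paste0('<line class="edge %s" x1="%.3f" y1="%.3f" x2="%.3f" ',
             'y2="%.3f" stroke="%s" stroke-width="%.2f"%s/>'),
      e$provenance[i], px[i1], py[i1], px[i2], py[i2],
      s$edge_color, s$edge_width, marker)
  }
  out <- c(out, '<g class="edges">', edge_lines, "</g>")

  glyphs <- character(nrow(network$vertices))
  for (i in seq_len(nrow(network$vertices))) {
    gl <- glyph_for_vertex(network, i, gray = s$gray)
    cx <- px[i]
    cy <- py[i]
    body <- if (gl$shape == "dot") {
      sprintf('<circle cx="%.3f" cy="%.3f" r="%.2f" fill="%s"/>',
              cx, cy, s$dot_radius, s$gray)
    } else {
      rx <- s$glyph_radius * if (gl$shape == "ellipse") s$ellipse_aspect_x else 1
      ry <- s$glyph_radius * if (gl$shape == "ellipse") s$ellipse_aspect_y else 1
      paste(vapply(seq_len(nrow(gl$sectors)), function(j) {
        sector_path(cx, cy, rx, ry, gl$sectors$start[j], gl$sectors$end[j],
                    gl$sectors$fill[j], s$stroke, s$stroke_width)
      }, ""), collapse = "")
    }
    label <- if (gl$shape == "dot") "" else {
      sprintf(paste0('<text x="%.3f" y="%.3f" font-size="%d" ',
                     'text-anchor="middle" font-family="sans-serif">',
                     "%s</text>"),
              cx, cy + s$glyph_radius + s$label_size,
              s$label_size, xml_escape(network$vertices$id[i]))
    }
    glyphs[i] <- sprintf('<g class="glyph %s" id="glyph-%s">%s%s</g>',
                         network$vertices$vkind[i],
                         xml_escape(network$vertices$id[i]), body, label)
  }
  out <- c(out, '<g class="glyphs">', glyphs, "</g>")

  # color-scale legend
  lw <- 120
  lx <- s$width - lw - 20
  ly <- s$height - 34
  clip <- network$clip %||% 1
  out <- c(
    out,
    '<g class="legend">',
    sprintf(paste0('<rect x="%d" y="%d" width="%d" height="10" ',
                   'fill="url(#fcscale)" stroke="%s" stroke-width="0.5"/>'),
            lx, ly, lw, s$stroke),
    sprintf(paste0('<text x="%d" y="%d" font-size="9" ',
                   'font-family="sans-serif">-%.2g</text>'),
            lx, ly + 22, clip),
    sprintf(paste0('<text x="%d" y="%d" font-size="9" text-anchor="end" ',
                   'font-family="sans-serif">+%.2g</text>'),
            lx + lw, ly + 22, clip),
    sprintf(paste0('<text x="%d" y="%d" font-size="9" text-anchor="middle" ',
                   'font-family="sans-serif">log2 fold change</text>'),
            lx + lw %/% 2, ly - 4),
    "</g>",
    "</svg>")
  svg <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(svg, path, useBytes = TRUE)
    return(invisible(svg))
  }
  svg
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
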