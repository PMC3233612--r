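# Fixed 32-colour qualitative palette for phams, cycled by pham number.
# Orphams are always white. Derived once from evenly spaced hues at two
# saturation/value levels so neighbouring pham numbers contrast.
pham_palette <- function() {
  if (!is.null(.pham_env$palette)) return(.pham_env$palette)
  h <- (seq(0, 15) * 0.618033988749895) %% 1
  pal <- c(grDevices::hsv(h, 0.55, 0.90), grDevices::hsv(h, 0.80, 0.70))
  .pham_env$palette <- pal
  pal
}

#' Colour assigned to a pham
#'
#' A pure function of the pham number: the fixed 32-colour palette is
#' cycled by number, and orphams are always white.
#'
#' @param number pham number.
#' @param is_orpham logical; orphams render white.
#' @return hex colour string.
#' @export
pham_color <- function(number, is_orpham = FALSE) {
  ifelse(is_orpham, "#FFFFFF",
         pham_palette()[((as.integer(number) - 1) %% 32) + 1])
}

map_geom <- list(margin_x = 150, margin_y = 40, row_gap = 110,
                 tier_gap = 60, box_h = 18, box_off = 4, label_h = 10,
                 shade_pad = 26)

#' Lay out stacked comparative genome maps
#'
#' Computes the deterministic geometry of a stack of linear genome
#' maps: each genome is a horizontal baseline with gene boxes above it
#' (forward strand) or below (reverse strand), filled by pham colour
#' (white for orphams), labelled with the gene name inside and the pham
#' number plus member count above. Between each pair of vertically
#' adjacent genomes, whole-genome nucleotide matches passing the 1e-4
#' threshold are drawn as shading quadrilaterals coloured by E-value
#' (violet = identical, red = at threshold). Genomes longer than
#' `wrap_bp` wrap into additional tiers; shading is drawn only for
#' matches falling within a single tier on both genomes.
#'
#' @param db a `pham_db`.
#' @param phage_order character vector of phage names, top to bottom.
#' @param scale bp per x-unit (default 50).
#' @param show_domains draw stored conserved-domain hits as yellow
#'   sub-boxes clipped to their gene box.
#' @param wrap_bp wrap genomes longer than this many bp (default Inf).
#' @return a `map_layout` list (rows, genes, shading, domains, geometry).
#' @export
layout_map <- function(db, phage_order, scale = 50, show_domains = FALSE,
                       wrap_bp = Inf) {
  stopifnot(inherits(db, "pham_db"), length(phage_order) >= 1)
  missing <- setdiff(phage_order, db$phage$name)
  if (length(missing) > 0) stop("unknown phage: ", missing[1])
  g <- map_geom
  nph <- length(phage_order)
  pham_sizes <- setNames(db$pham$size, db$pham$number)

  tiers_of <- function(len) if (is.finite(wrap_bp))
    max(1L, ceiling(len / wrap_bp)) else 1L
  phage_rows <- db$phage[match(phage_order, db$phage$name), , drop = FALSE]
  n_tiers <- max(vapply(phage_rows$length_bp, tiers_of, integer(1)))
  tier_height <- (nph - 1) * g$row_gap + 2 * g$shade_pad

  row_y <- function(p_idx, tier)
    g$margin_y + g$shade_pad + tier * (tier_height + g$tier_gap) +
      (p_idx - 1) * g$row_gap

  rows <- list(); genes <- list(); shading <- list(); domains <- list()
  for (i in seq_len(nph)) {
    ph <- phage_rows[i, ]
    for (tier in 0:(tiers_of(ph$length_bp) - 1L)) {
      seg_start <- tier * if (is.finite(wrap_bp)) wrap_bp else 0
      seg_len <- if (is.finite(wrap_bp))
        min(wrap_bp, ph$length_bp - seg_start) else ph$length_bp
      rows[[length(rows) + 1]] <- data.frame(
        phage = ph$name, tier = tier, y = row_y(i, tier),
        x0 = g$margin_x, x1 = g$margin_x + seg_len / scale,
        seg_start = seg_start, stringsAsFactors = FALSE)
    }
    gg <- db$gene[db$gene$phage == ph$name, , drop = FALSE]
    for (k in seq_len(nrow(gg))) {
      tier <- if (is.finite(wrap_bp)) gg$start[k] %/% wrap_bp else 0L
      seg_start <- tier * if (is.finite(wrap_bp)) wrap_bp else 0
      y <- row_y(i, tier)
      fwd <- gg$strand[k] == "forward"
      pn <- gg$pham_number[k]
      orph <- !is.na(pn) && isTRUE(pham_sizes[as.character(pn)] == 1L)
      genes[[length(genes) + 1]] <- data.frame(
        phage = ph$name, gene_id = gg$gene_id[k], label = gg$name[k],
        pham_label = if (is.na(pn)) "" else
          sprintf("%d (%d)", pn, pham_sizes[as.character(pn)]),
        x = g$margin_x + (gg$start[k] - seg_start) / scale,
        w = (gg$stop[k] - gg$start[k]) / scale,
        y = if (fwd) y - g$box_off - g$box_h else y + g$box_off,
        h = g$box_h, strand = gg$strand[k],
        fill = if (is.na(pn)) "#FFFFFF" else pham_color(pn, orph),
        stringsAsFactors = FALSE)
      if (show_domains && nrow(db$domain) > 0) {
        dh <- db$domain[db$domain$gene_id == gg$gene_id[k], , drop = FALSE]
        for (d in seq_len(nrow(dh))) {
          aa0 <- dh$query_start[d]; aa1 <- dh$query_end[d]
          if (gg$strand[k] == "forward") {
            b0 <- gg$start[k] + 3 * aa0; b1 <- gg$start[k] + 3 * aa1
          } else {
            b0 <- gg$stop[k] - 3 * aa1; b1 <- gg$stop[k] - 3 * aa0
          }
          domains[[length(domains) + 1]] <- data.frame(
            gene_id = gg$gene_id[k],
            x = g$margin_x + (b0 - seg_start) / scale,
            w = (b1 - b0) / scale,
            y = (if (fwd) y - g$box_off - g$box_h else y + g$box_off) +
              g$box_h / 3,
            h = g$box_h / 3,
            title = sprintf("%s %s", dh$domain_accession[d],
                            dh$description[d]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  # shading between vertically adjacent genomes only
  for (i in seq_len(nph - 1)) {
    pa <- db_get_phage(db, phage_order[i])
    pb <- db_get_phage(db, phage_order[i + 1])
    m <- genome_alignments(pa, pb, db$config)
    for (k in seq_len(nrow(m))) {
      ta <- if (is.finite(wrap_bp)) m$a_start[k] %/% wrap_bp else 0L
      tb <- if (is.finite(wrap_bp)) m$b_start[k] %/% wrap_bp else 0L
      if (ta != tb) next
      if (is.finite(wrap_bp) &&
          (m$a_end[k] > (ta + 1) * wrap_bp || m$b_end[k] > (tb + 1) * wrap_bp))
        next
      seg <- ta * if (is.finite(wrap_bp)) wrap_bp else 0
      y_top <- row_y(i, ta) + g$shade_pad
      y_bot <- row_y(i + 1, ta) - g$shade_pad
      same <- m$orientation[k] == "same"
      shading[[length(shading) + 1]] <- data.frame(
        ax0 = g$margin_x + (m$a_start[k] - seg) / scale,
        ax1 = g$margin_x + (m$a_end[k] - seg) / scale,
        bx0 = g$margin_x + (m[[if (same) "b_start" else "b_end"]][k] - seg) / scale,
        bx1 = g$margin_x + (m[[if (same) "b_end" else "b_start"]][k] - seg) / scale,
        y_top = y_top, y_bot = y_bot,
        fill = evalue_to_color(m$evalue[k],
                               db$config$nucleotide_evalue_threshold),
        orientation = m$orientation[k], stringsAsFactors = FALSE)
    }
  }

  bind0 <- function(lst, proto) if (length(lst) > 0) do.call(rbind, lst) else proto
  rows <- bind0(rows, NULL)
  width <- max(rows$x1) + 40
  height <- g$margin_y + g$shade_pad + (n_tiers - 1) * (tier_height + g$tier_gap) +
    (nph - 1) * g$row_gap + g$shade_pad + g$margin_y
  structure(list(
    rows = rows,
    genes = bind0(genes, data.frame()),
    shading = bind0(shading, data.frame()),
    domains = bind0(domains, data.frame()),
    scale = scale, wrap_bp = wrap_bp, width = width, height = height),
    class = "map_layout")
}

db_get_phage <- function(db, name) {
  r <- db$phage[db$phage$name == name, , drop = FALSE]
  if (nrow(r) == 0) stop("unknown phage: ", name)
  genes <- db$gene[db$gene$phage == name,
                   setdiff(names(db$gene), "phage"), drop = FALSE]
  new_phage(r$name, r$sequence, genes, accession = r$accession,
            cluster = r$cluster, subcluster = r$subcluster)
}

fmt <- function(x) sprintf("%.2f", x)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

#' Render a map layout as SVG text
#'
#' Deterministic: identical layouts give byte-identical SVG. Gene boxes
#' carry `<title>` elements with gene id and pham label; domain boxes
#' carry their domain description.
#'
#' @param layout a [layout_map()] result.
#' @return a single SVG string.
#' @export
render_map <- function(layout) {
  stopifnot(inherits(layout, "map_layout"))
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
    fmt(layout$width), fmt(layout$height), fmt(layout$width),
    fmt(layout$height)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="white"/>',
            fmt(layout$width), fmt(layout$height)))
  s <- layout$shading
  for (k in seq_len(NROW(s))) {
    out <- c(out, sprintf(
      '<polygon points="%s,%s %s,%s %s,%s %s,%s" fill="%s" fill-opacity="0.55" stroke="none"/>',
      fmt(s$ax0[k]), fmt(s$y_top[k]), fmt(s$ax1[k]), fmt(s$y_top[k]),
      fmt(s$bx1[k]), fmt(s$y_bot[k]), fmt(s$bx0[k]), fmt(s$y_bot[k]),
      s$fill[k]))
  }
  r <- layout$rows
  for (k in seq_len(NROW(r))) {
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1"/>',
      fmt(r$x0[k]), fmt(r$y[k]), fmt(r$x1[k]), fmt(r$y[k])),
      sprintf('<text x="%s" y="%s" font-size="12" text-anchor="end" font-family="sans-serif">%s</text>',
              fmt(r$x0[k] - 8), fmt(r$y[k] + 4),
              xml_escape(paste0(r$phage[k],
                                if (r$tier[k] > 0) sprintf(" (tier %d)", r$tier[k] + 1) else ""))))
  }
  ge <- layout$genes
  for (k in seq_len(NROW(ge))) {
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="black" stroke-width="0.75"><title>%s</title></rect>',
      fmt(ge$x[k]), fmt(ge$y[k]), fmt(ge$w[k]), fmt(ge$h[k]), ge$fill[k],
      xml_escape(paste(ge$gene_id[k], ge$pham_label[k]))),
      sprintf('<text x="%s" y="%s" font-size="9" text-anchor="middle" font-family="sans-serif">%s</text>',
              fmt(ge$x[k] + ge$w[k] / 2), fmt(ge$y[k] + ge$h[k] / 2 + 3),
              xml_escape(ge$label[k])))
    if (nzchar(ge$pham_label[k])) {
      lab_y <- if (ge$strand[k] == "forward") ge$y[k] - 3
               else ge$y[k] + ge$h[k] + 9
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="8" text-anchor="middle" font-family="sans-serif" fill="#444444">%s</text>',
        fmt(ge$x[k] + ge$w[k] / 2), fmt(lab_y),
        xml_escape(ge$pham_label[k])))
    }
  }
  d <- layout$domains
  for (k in seq_len(NROW(d))) {
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="#FFD700" stroke="#B8860B" stroke-width="0.5"><title>%s</title></rect>',
      fmt(d$x[k]), fmt(d$y[k]), fmt(d$w[k]), fmt(d$h[k]),
      xml_escape(d$title[k])))
  }
  paste0(paste(c(out, "</svg>"), collapse = "\n"), "\n")
}

#' Lay out a phamily circle
#'
#' Every phage in the database is placed once on the circumference,
#' ordered by cluster, subcluster and name, and coloured by cluster.
#' Phages containing members of the selected pham get the member gene
#' names appended to their label. For every pair of genomes holding
#' related members, arcs are drawn: blue when the best percent identity
#' between their members meets the identity threshold, red when the
#' best E-value meets the E-value threshold; both may be superimposed.
#' Arc width scales with the strength of the relationship (identity for
#' blue, capped -log10 E for red).
#'
#' @param db a `pham_db`.
#' @param pham_number an existing pham number.
#' @return a `circle_layout` list (nodes, arcs, geometry).
#' @export
layout_circle <- function(db, pham_number) {
  stopifnot(inherits(db, "pham_db"))
  if (!pham_number %in% db$pham$number)
    stop("no such pham: ", pham_number)
  ph <- db$phage
  ord <- order(ph$cluster, ph$subcluster, ph$name, na.last = TRUE)
  ph <- ph[ord, , drop = FALSE]
  n <- nrow(ph)
  cx <- 300; cy <- 300; radius <- 210
  ang <- -pi / 2 + 2 * pi * (seq_len(n) - 1) / n
  members <- db$gene[!is.na(db$gene$pham_number) &
                       db$gene$pham_number == pham_number, , drop = FALSE]
  member_label <- vapply(ph$name, function(p) {
    gn <- members$name[members$phage == p]
    if (length(gn) == 0) "" else paste0(" (", paste(sort(gn), collapse = ","), ")")
  }, character(1))
  cluster_idx <- match(ph$cluster, sort(unique(ph$cluster)))
  nodes <- data.frame(
    phage = ph$name, cluster = ph$cluster, subcluster = ph$subcluster,
    angle = ang, x = cx + radius * cos(ang), y = cy + radius * sin(ang),
    label = paste0(ph$name, member_label),
    color = pham_palette()[((cluster_idx - 1) %% 32) + 1],
    has_member = nzchar(member_label), stringsAsFactors = FALSE)

  cfg <- db$config
  e <- derive_edges(db$scores, database_residues(db), cfg)
  e <- e[e$gene_a %in% members$gene_id & e$gene_b %in% members$gene_id, ,
         drop = FALSE]
  phage_of <- setNames(members$phage, members$gene_id)
  arcs <- list()
  if (nrow(e) > 0) {
    e$phage_a <- unname(phage_of[e$gene_a])
    e$phage_b <- unname(phage_of[e$gene_b])
    e <- e[e$phage_a != e$phage_b, , drop = FALSE]
    if (nrow(e) > 0) {
      pr_a <- pmin(e$phage_a, e$phage_b)
      pr_b <- pmax(e$phage_a, e$phage_b)
      key <- paste(pr_a, pr_b, sep = "\r")
      best_pid <- tapply(e$percent_identity, key, max)
      best_ev <- tapply(e$evalue, key, min)
      for (k in names(best_pid)) {
        pp <- strsplit(k, "\r", fixed = TRUE)[[1]]
        if (best_pid[[k]] >= cfg$identity_threshold)
          arcs[[length(arcs) + 1]] <- data.frame(
            phage_a = pp[1], phage_b = pp[2], type = "identity",
            color = "#0000CC", value = best_pid[[k]],
            width = 0.75 + 2.25 * (best_pid[[k]] - cfg$identity_threshold) /
              (100 - cfg$identity_threshold),
            stringsAsFactors = FALSE)
        if (best_ev[[k]] <= cfg$evalue_threshold)
          arcs[[length(arcs) + 1]] <- data.frame(
            phage_a = pp[1], phage_b = pp[2], type = "evalue",
            color = "#CC0000", value = best_ev[[k]],
            width = 0.75 + 2.25 *
              min(-log10(max(best_ev[[k]], 1e-300)), 300) / 300,
            stringsAsFactors = FALSE)
      }
    }
  }
  arcs <- if (length(arcs) > 0) do.call(rbind, arcs) else
    data.frame(phage_a = character(0), phage_b = character(0),
               type = character(0), color = character(0),
               value = numeric(0), width = numeric(0),
               stringsAsFactors = FALSE)
  arcs <- arcs[order(arcs$phage_a, arcs$phage_b,
                     arcs$type, method = "radix"), , drop = FALSE]
  rownames(arcs) <- NULL
  structure(list(pham_number = pham_number, nodes = nodes, arcs = arcs,
                 cx = cx, cy = cy, radius = radius, width = 600,
                 height = 620), class = "circle_layout")
}

#' Render a phamily circle layout as SVG text
#'
#' Deterministic byte-for-byte for a given layout. Red (E-value) arcs
#' are drawn first so superimposed blue (identity) arcs stay visible.
#'
#' @param layout a [layout_circle()] result.
#' @return a single SVG string.
#' @export
render_circle <- function(layout) {
  stopifnot(inherits(layout, "circle_layout"))
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
    fmt(layout$width), fmt(layout$height), fmt(layout$width),
    fmt(layout$height)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="white"/>',
            fmt(layout$width), fmt(layout$height)),
    sprintf('<text x="%s" y="20" font-size="14" text-anchor="middle" font-family="sans-serif">Pham %d</text>',
            fmt(layout$cx), layout$pham_number),
    sprintf('<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#CCCCCC" stroke-width="1"/>',
            fmt(layout$cx), fmt(layout$cy), fmt(layout$radius)))
  nd <- layout$nodes
  pos <- setNames(seq_len(NROW(nd)), nd$phage)
  a <- layout$arcs
  for (type in c("evalue", "identity")) {
    sel <- which(a$type == type)
    for (k in sel) {
      p1 <- pos[[a$phage_a[k]]]; p2 <- pos[[a$phage_b[k]]]
      x1 <- nd$x[p1]; y1 <- nd$y[p1]; x2 <- nd$x[p2]; y2 <- nd$y[p2]
      qx <- layout$cx + 0.25 * ((x1 + x2) / 2 - layout$cx)
      qy <- layout$cy + 0.25 * ((y1 + y2) / 2 - layout$cy)
      out <- c(out, sprintf(
        '<path d="M %s %s Q %s %s %s %s" fill="none" stroke="%s" stroke-width="%s" stroke-opacity="0.65"/>',
        fmt(x1), fmt(y1), fmt(qx), fmt(qy), fmt(x2), fmt(y2),
        a$color[k], fmt(a$width[k])))
    }
  }
  for (k in seq_len(NROW(nd))) {
    anchor <- if (cos(nd$angle[k]) < -1e-9) "end" else "start"
    lx <- nd$x[k] + 12 * cos(nd$angle[k])
    ly <- nd$y[k] + 12 * sin(nd$angle[k]) + 3
    out <- c(out, sprintf(
      '<circle cx="%s" cy="%s" r="4" fill="%s" stroke="black" stroke-width="0.5"/>',
      fmt(nd$x[k]), fmt(nd$y[k]), nd$color[k]),
      sprintf('<text x="%s" y="%s" font-size="10" text-anchor="%s" font-family="sans-serif"%s>%s</text>',
              fmt(lx), fmt(ly), anchor,
              if (nd$has_member[k]) ' font-weight="bold"' else "",
              xml_escape(nd$label[k])))
  }
  paste0(paste(c(out, "</svg>"), collapse = "\n"), "\n")
}
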