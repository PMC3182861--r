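# Branched neuron morphologies: surrogate generation, SWC I/O, discretization.
#
# A morphology is a tree of tapered cylindrical sections. The soma is the
# single root section (modelled as a cylinder with length = diameter); all
# other sections are dendritic frusta. Sections are stored in a data.frame
# ordered so that every parent precedes its children, which is the order the
# cable solver relies on.

#' Morphology generator configuration
#'
#' Encodes the aggregate morphometric targets the surrogate generator must
#' hit: total membrane area, total dendritic length, longest soma-to-tip
#' path, section/segment counts and the number of primary dendrites. The
#' defaults reproduce the printed morphometrics of the reconstructed mouse
#' dLGN interneuron used throughout (9864 um^2, 5771 um of dendrite, longest
#' dendrite 673 um, 104 sections discretized into 330 segments).
#'
#' @param target_area total membrane area in um^2 (soma + dendrites)
#' @param target_dendrite_length summed dendritic section length, um
#' @param target_longest_path longest path from soma to a dendritic tip, um
#' @param mean_diameter nominal length-weighted mean dendritic diameter, um.
#'   Used only as a consistency check: area and length together imply the
#'   mean diameter, and a config whose implied value deviates more than 25%
#'   from `mean_diameter` is rejected as infeasible.
#' @param n_sections total number of sections including the soma
#' @param n_segments total number of segments after discretization
#' @param n_primary_dendrites number of dendritic stems leaving the soma;
#'   0 gives a soma-only morphology
#' @param seed integer seed controlling length/branching jitter
#' @param soma_length,soma_diameter soma cylinder dimensions, um
#' @return an object of class `morpho_config`
#' @export
morpho_config <- function(target_area = 9864,
                          target_dendrite_length = 5771,
                          target_longest_path = 673,
                          mean_diameter = 0.5,
                          n_sections = 104,
                          n_segments = 330,
                          n_primary_dendrites = 6,
                          seed = 1L,
                          soma_length = 16,
                          soma_diameter = 16) {
  cfg <- list(target_area = target_area,
              target_dendrite_length = target_dendrite_length,
              target_longest_path = target_longest_path,
              mean_diameter = mean_diameter,
              n_sections = as.integer(n_sections),
              n_segments = as.integer(n_segments),
              n_primary_dendrites = as.integer(n_primary_dendrites),
              seed = as.integer(seed),
              soma_length = soma_length,
              soma_diameter = soma_diameter)
  class(cfg) <- "morpho_config"
  validate_morpho_config(cfg)
  cfg
}

validate_morpho_config <- function(cfg) {
  if (cfg$n_primary_dendrites > 0L) {
    for (f in c("target_area", "target_dendrite_length", "target_longest_path",
                "mean_diameter"))
      if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
        stop("morpho_config: '", f, "' must be positive", call. = FALSE)
  }
  if (cfg$n_sections < 1L)
    stop("morpho_config: need at least one section (the soma)", call. = FALSE)
  if (cfg$n_segments < cfg$n_sections)
    stop("morpho_config: n_segments must be >= n_sections", call. = FALSE)
  if (cfg$n_primary_dendrites > 0L &&
      cfg$n_sections - 1L < cfg$n_primary_dendrites)
    stop("morpho_config: fewer dendritic sections than primary dendrites",
         call. = FALSE)
  invisible(cfg)
}

#' Configurations for the four morphology variants
#'
#' Returns the generator configuration for the original surrogate morphology
#' ("o") or for the three alternative-area variants used in the
#' morphology-dependence experiment: (a) similar (9566 um^2), (b) smaller
#' (7071 um^2) and (c) larger (14336 um^2) total membrane area. Dendritic
#' length and longest path are scaled with the dendritic area so that the
#' mean diameter stays fixed; only total areas are printed for the variants.
#'
#' @param which one of "o", "a", "b", "c"
#' @param seed generator seed
#' @return a `morpho_config`
#' @export
morpho_variant <- function(which = c("o", "a", "b", "c"), seed = 1L) {
  which <- match.arg(which)
  areas <- c(o = 9864, a = 9566, b = 7071, c = 14336)
  base <- morpho_config(seed = seed)
  if (which == "o") return(base)
  soma_area <- pi * base$soma_diameter * base$soma_length
  scale <- (areas[[which]] - soma_area) / (base$target_area - soma_area)
  morpho_config(target_area = areas[[which]],
                target_dendrite_length = base$target_dendrite_length * scale,
                target_longest_path = base$target_longest_path * scale,
                mean_diameter = base$mean_diameter,
                seed = seed)
}

new_morphology <- function(sections, name = "morphology", coords = NULL) {
  m <- list(name = name, sections = sections, coords = coords)
  class(m) <- "in_morphology"
  validate_morphology(m)
  m
}

#' Validate a morphology object
#'
#' Checks the structural invariants: positive lengths and diameters, exactly
#' one root which must be the soma, parents preceding children, and an
#' acyclic connected tree.
#'
#' @param m an `in_morphology`
#' @return `m`, invisibly; stops on violation
#' @export
validate_morphology <- function(m) {
  s <- m$sections
  need <- c("id", "parent_id", "kind", "length", "diam_prox", "diam_dist", "nseg")
  if (!all(need %in% names(s)))
    stop("morphology: missing columns: ",
         paste(setdiff(need, names(s)), collapse = ", "), call. = FALSE)
  if (any(s$length <= 0) || any(s$diam_prox <= 0) || any(s$diam_dist <= 0))
    stop("morphology: lengths and diameters must be positive", call. = FALSE)
  if (any(s$nseg < 1L))
    stop("morphology: nseg must be >= 1", call. = FALSE)
  roots <- which(is.na(s$parent_id))
  if (length(roots) != 1L)
    stop("morphology: expected exactly one root section, found ",
         length(roots), call. = FALSE)
  if (s$kind[roots] != "soma")
    stop("morphology: root section must be the soma", call. = FALSE)
  if (sum(s$kind == "soma") != 1L)
    stop("morphology: exactly one soma section expected", call. = FALSE)
  idx <- match(s$parent_id, s$id)
  bad <- which(!is.na(s$parent_id) & is.na(idx))
  if (length(bad))
    stop("morphology: section ", s$id[bad[1]], " references unknown parent ",
         s$parent_id[bad[1]], call. = FALSE)
  if (any(idx[!is.na(idx)] >= which(!is.na(s$parent_id) & !is.na(idx))))
    stop("morphology: parents must precede children", call. = FALSE)
  invisible(m)
}

soma_row <- function(m) which(m$sections$kind == "soma")

#' Total membrane surface area
#'
#' Sum of the lateral areas of the tapered dendritic cylinders (frusta, using
#' the slant length) plus the lateral area of the soma cylinder.
#'
#' @param m an `in_morphology`
#' @return area in um^2
#' @export
surface_area <- function(m) {
  s <- m$sections
  sum(section_lateral_area(s$length, s$diam_prox, s$diam_dist))
}

# Frustum lateral area pi*(r1+r2)*slant; for a cylinder this is pi*d*L.
section_lateral_area <- function(length, d1, d2) {
  r1 <- d1 / 2; r2 <- d2 / 2
  slant <- sqrt(length^2 + (r1 - r2)^2)
  pi * (r1 + r2) * slant
}

#' Total dendritic length
#' @param m an `in_morphology`
#' @return summed length of dendritic sections, um
#' @export
dendrite_length <- function(m) {
  s <- m$sections
  sum(s$length[s$kind != "soma"])
}

#' Path distance from the soma
#'
#' Arc length from the soma boundary to a point on a section. Any point
#' inside the soma has distance 0; dendritic distance is measured from the
#' soma-dendrite junction, matching the convention used by the
#' distance-dependent channel density rules.
#'
#' @param m an `in_morphology`
#' @param section_id id of the section
#' @param fraction position along the section in `[0, 1]`
#' @return distance in um
#' @export
path_distance <- function(m, section_id, fraction = 0.5) {
  s <- m$sections
  i <- match(section_id, s$id)
  if (is.na(i)) stop("unknown section id: ", section_id, call. = FALSE)
  stopifnot(fraction >= 0, fraction <= 1)
  if (s$kind[i] == "soma") return(0)
  d <- s$length[i] * fraction
  p <- s$parent_id[i]
  while (!is.na(p)) {
    j <- match(p, s$id)
    if (s$kind[j] == "soma") break
    d <- d + s$length[j]
    p <- s$parent_id[j]
  }
  d
}

#' Longest soma-to-tip path
#' @param m an `in_morphology`
#' @return maximal `path_distance` over dendritic tips, um
#' @export
longest_path <- function(m) {
  s <- m$sections
  dend <- s$id[s$kind != "soma"]
  if (!length(dend)) return(0)
  tips <- setdiff(dend, s$parent_id)
  max(vapply(tips, function(id) path_distance(m, id, 1), numeric(1)))
}

#' Generate a surrogate morphology matching aggregate morphometrics
#'
#' Builds a branched dendritic tree of tapered cylinders around a cylindrical
#' soma so that the total membrane area, total dendritic length, longest
#' soma-to-tip path, and the section and segment counts match the targets in
#' `config` (areas and lengths are rescaled to hit the targets essentially
#' exactly). One primary dendrite is an unbranched chain realizing the
#' longest path; the remaining stems carry near-balanced binary subtrees with
#' seeded length jitter. Diameters taper geometrically along the tree and are
#' scaled as a whole to meet the area target.
#'
#' @param config a [morpho_config()]
#' @return an `in_morphology`, already discretized to `config$n_segments`
#' @export
generate_surrogate <- function(config = morpho_config()) {
  validate_morpho_config(config)
  soma_area <- pi * config$soma_diameter * config$soma_length
  soma <- data.frame(id = 1L, parent_id = NA_integer_, kind = "soma",
                     length = config$soma_length,
                     diam_prox = config$soma_diameter,
                     diam_dist = config$soma_diameter,
                     nseg = 1L, stringsAsFactors = FALSE)
  if (config$n_primary_dendrites == 0L) {
    m <- new_morphology(soma, name = sprintf("surrogate-area%.0f", soma_area))
    return(m)
  }
  if (config$target_area <= soma_area)
    stop("surrogate generation infeasible: target_area (", config$target_area,
         " um^2) does not exceed the soma area (", round(soma_area, 1),
         " um^2)", call. = FALSE)
  implied_mean <- (config$target_area - soma_area) /
    (pi * config$target_dendrite_length)
  if (abs(implied_mean - config$mean_diameter) / config$mean_diameter > 0.25)
    stop("surrogate generation infeasible: area and dendritic length imply ",
         "a mean diameter of ", signif(implied_mean, 3), " um, more than 25%",
         " away from the configured mean_diameter (", config$mean_diameter,
         " um)", call. = FALSE)
  if (config$target_longest_path > config$target_dendrite_length)
    stop("surrogate generation infeasible: target_longest_path exceeds the ",
         "total target_dendrite_length", call. = FALSE)

  n_dend <- config$n_sections - 1L
  n_stem <- config$n_primary_dendrites
  rng <- local_rng(config$seed)

  # Partition dendritic sections among stems. Stem 1 is the unbranched chain
  # that realizes the longest path; give it roughly n_dend / (2 * n_stem)
  # sections (at least 2 when possible).
  n_chain <- max(min(2L, n_dend), min(n_dend - (n_stem - 1L),
                                      as.integer(round(n_dend / (2 * n_stem)))))
  rest <- n_dend - n_chain
  n_per <- if (n_stem > 1L) {
    base <- rest %/% (n_stem - 1L)
    extra <- rest %% (n_stem - 1L)
    base + as.integer(seq_len(n_stem - 1L) <= extra)
  } else integer(0)
  if (n_stem > 1L && any(n_per < 1L))
    stop("surrogate generation infeasible: too few sections for ",
         n_stem, " primary dendrites", call. = FALSE)

  sec <- list()
  next_id <- 2L
  add_sec <- function(parent, depth) {
    row <- data.frame(id = next_id, parent_id = parent, kind = "dend",
                      length = NA_real_, diam_prox = NA_real_,
                      diam_dist = NA_real_, nseg = 1L,
                      depth = depth, stringsAsFactors = FALSE)
    next_id <<- next_id + 1L
    row
  }

  # Chain stem.
  chain_rows <- list()
  parent <- 1L
  for (k in seq_len(n_chain)) {
    r <- add_sec(parent, k - 1L)
    parent <- r$id
    chain_rows[[k]] <- r
  }
  chain <- do.call(rbind, chain_rows)
  jit <- rng(nrow(chain))            # in [0, 1)
  raw <- 0.8 + 0.4 * jit
  chain$length <- raw * (config$target_longest_path / sum(raw))

  # Branched stems: breadth-first balanced binary trees with jittered,
  # depth-decaying lengths.
  stems <- list(chain)
  for (s_i in seq_len(n_stem - 1L)) {
    n_i <- n_per[s_i]
    rows <- list()
    open <- integer(0)                 # ids with < 2 children
    children <- new.env()
    for (k in seq_len(n_i)) {
      if (k == 1L) par <- 1L
      else {
        par <- open[1L]
        cnt <- get0(as.character(par), envir = children, ifnotfound = 0L)
        assign(as.character(par), cnt + 1L, envir = children)
        if (cnt + 1L >= 2L) open <- open[-1L]
      }
      depth <- if (k == 1L) 0L else rows[[which(vapply(rows, function(r) r$id, integer(1)) == par)]]$depth + 1L
      r <- add_sec(par, depth)
      rows[[k]] <- r
      open <- c(open, r$id)
    }
    tr <- do.call(rbind, rows)
    tr$length <- (0.85 ^ tr$depth) * (0.8 + 0.4 * rng(nrow(tr)))
    stems[[s_i + 1L]] <- tr
  }
  dend <- do.call(rbind, stems)

  # Rescale the branched stems so the total dendritic length is exact, while
  # keeping every branched path strictly shorter than the chain.
  if (n_stem > 1L) {
    other <- dend$id %in% do.call(rbind, stems[-1])$id
    need <- config$target_dendrite_length - config$target_longest_path
    if (need <= 0)
      stop("surrogate generation infeasible: target_dendrite_length must ",
           "exceed target_longest_path when there are several stems",
           call. = FALSE)
    dend$length[other] <- dend$length[other] * (need / sum(dend$length[other]))
    # The chain must remain the longest path.
    pl <- tree_tip_paths(dend)
    if (any(pl$path[pl$branched] >= 0.99 * config$target_longest_path))
      stop("surrogate generation infeasible: a branched stem reaches the ",
           "target_longest_path; adjust n_sections or targets", call. = FALSE)
  } else if (abs(sum(dend$length) - config$target_dendrite_length) >
             1e-6 * config$target_dendrite_length) {
    dend$length <- dend$length *
      (config$target_dendrite_length / sum(dend$length))
  }

  # Diameters: geometric taper with depth, continuous across branch points,
  # globally scaled to hit the area target.
  taper <- 0.8
  dend$diam_prox <- taper ^ dend$depth
  dend$diam_dist <- taper ^ (dend$depth + 1L)
  area_at <- function(k) {
    sum(section_lateral_area(dend$length, k * dend$diam_prox,
                             k * dend$diam_dist))
  }
  target_dend_area <- config$target_area - soma_area
  f <- function(k) area_at(k) - target_dend_area
  k <- tryCatch(stats::uniroot(f, c(1e-4, 1e3), tol = 1e-12)$root,
                error = function(e)
                  stop("surrogate generation infeasible: cannot reach ",
                       "target_area ", config$target_area, " um^2 by scaling ",
                       "diameters", call. = FALSE))
  dend$diam_prox <- k * dend$diam_prox
  dend$diam_dist <- k * dend$diam_dist

  dend$depth <- NULL
  sections <- rbind(soma, dend)
  m <- new_morphology(sections,
                      name = sprintf("surrogate-seed%d-area%.0f",
                                     config$seed, config$target_area))
  m$config <- config
  discretize(m, n_total = config$n_segments)
}

# Deterministic uniform stream independent of the global RNG state.
local_rng <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  if (state <= 0) state <- state + 2147483646
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 16807) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}

# Root-to-tip path length per tip for a dendrite table (depth-first ids).
tree_tip_paths <- function(dend) {
  cum <- numeric(nrow(dend))
  stem <- integer(nrow(dend))
  for (i in seq_len(nrow(dend))) {
    p <- dend$parent_id[i]
    j <- match(p, dend$id)
    cum[i] <- dend$length[i] + if (is.na(j)) 0 else cum[j]
    stem[i] <- if (is.na(j)) dend$id[i] else stem[j]
  }
  tips <- !(dend$id %in% dend$parent_id)
  first_stem <- dend$id[which(is.na(match(dend$parent_id, dend$id)))[1]]
  data.frame(path = cum[tips], stem = stem[tips],
             branched = stem[tips] != first_stem)
}

#' Discretize a morphology into segments
#'
#' Sets the `nseg` count of every section. Two rules are available: a fixed
#' total (`n_total`), which distributes segments proportionally to section
#' length (largest-remainder rounding, soma fixed at 1) and is used to
#' reproduce the reference 330-segment discretization; or a maximum segment
#' length (`max_seg_length`), where `nseg = ceiling(length / max_seg_length)`.
#'
#' @param m an `in_morphology`
#' @param max_seg_length maximal segment length in um (rule 2)
#' @param n_total exact total number of segments (rule 1)
#' @return the morphology with `nseg` set
#' @export
discretize <- function(m, max_seg_length = NULL, n_total = NULL) {
  s <- m$sections
  if (!is.null(n_total)) {
    n_total <- as.integer(n_total)
    if (n_total < nrow(s))
      stop("n_total must be at least the number of sections", call. = FALSE)
    dend <- which(s$kind != "soma")
    s$nseg <- 1L
    extra <- n_total - nrow(s)
    if (extra > 0L && length(dend)) {
      w <- s$length[dend] / sum(s$length[dend])
      alloc <- floor(w * extra)
      rem <- extra - sum(alloc)
      if (rem > 0L) {
        frac <- w * extra - alloc
        ord <- order(frac, decreasing = TRUE)
        alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
      }
      s$nseg[dend] <- 1L + as.integer(alloc)
    }
  } else if (!is.null(max_seg_length)) {
    stopifnot(max_seg_length > 0)
    s$nseg <- pmax(1L, as.integer(ceiling(s$length / max_seg_length)))
    s$nseg[s$kind == "soma"] <- 1L
  } else {
    stop("supply either max_seg_length or n_total", call. = FALSE)
  }
  m$sections <- s
  m
}

#' Total number of segments
#' @param m an `in_morphology`
#' @return integer segment count
#' @export
n_segments <- function(m) sum(m$sections$nseg)

#' @export
print.in_morphology <- function(x, ...) {
  s <- x$sections
  cat("dLGN interneuron morphology:", x$name, "\n")
  cat(sprintf("  %d sections (%d dendritic), %d segments\n",
              nrow(s), sum(s$kind != "soma"), sum(s$nseg)))
  cat(sprintf("  total area %.1f um^2, dendritic length %.1f um, longest path %.1f um\n",
              surface_area(x), dendrite_length(x), longest_path(x)))
  invisible(x)
}

#' @export
summary.in_morphology <- function(object, ...) {
  s <- object$sections
  dend <- s[s$kind != "soma", ]
  out <- list(name = object$name,
              n_sections = nrow(s),
              n_segments = sum(s$nseg),
              area = surface_area(object),
              dendrite_length = dendrite_length(object),
              longest_path = longest_path(object),
              mean_diameter = if (nrow(dend))
                sum((dend$diam_prox + dend$diam_dist) / 2 * dend$length) /
                  sum(dend$length) else NA_real_)
  class(out) <- "summary.in_morphology"
  out
}

#' @export
print.summary.in_morphology <- function(x, ...) {
  cat("Morphology", x$name, "\n")
  cat(sprintf("  sections: %d  segments: %d\n", x$n_sections, x$n_segments))
  cat(sprintf("  area: %.1f um^2  dendritic length: %.1f um\n",
              x$area, x$dendrite_length))
  cat(sprintf("  longest path: %.1f um  mean dendritic diameter: %.3f um\n",
              x$longest_path, x$mean_diameter))
  invisible(x)
}

# ---------------------------------------------------------------------------
# SWC input/output.
#
# Convention: one SWC edge between samples of the same type is one section.
# The soma is written as a two-sample cylinder; a dendritic section is one
# sample (its distal end) whose parent sample provides the proximal position
# and radius. A stem (child of the soma) additionally writes an explicit
# proximal sample at the soma junction so its proximal radius is preserved;
# the soma->dendrite edge is an attachment, not geometry.

#' Write a morphology to an SWC file
#'
#' Synthetic morphologies are given a deterministic straight-line 3D
#' embedding (directions only matter for SWC validity; the electrical model
#' uses lengths and diameters alone).
#'
#' @param m an `in_morphology`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_swc <- function(m, path) {
  s <- m$sections
  ns <- nrow(s)
  # embedding: soma along +x from origin; stems fan out by golden-angle
  samples <- list()
  nsamp <- 0L
  add <- function(type, xyz, r, parent) {
    nsamp <<- nsamp + 1L
    samples[[nsamp]] <<- c(id = nsamp, type = type, x = xyz[1], y = xyz[2],
                           z = xyz[3], r = r, parent = parent)
    nsamp
  }
  i_soma <- soma_row(m)
  r_soma <- s$diam_prox[i_soma] / 2
  p0 <- add(1, c(0, 0, 0), r_soma, -1L)
  p1 <- add(1, c(s$length[i_soma], 0, 0), r_soma, p0)
  # per-section distal sample id, position, direction
  distal_samp <- integer(ns); distal_pos <- matrix(0, ns, 3)
  dirs <- matrix(0, ns, 3)
  distal_samp[i_soma] <- p1
  distal_pos[i_soma, ] <- c(s$length[i_soma], 0, 0)
  dirs[i_soma, ] <- c(1, 0, 0)
  child_rank <- integer(ns)
  golden <- pi * (3 - sqrt(5))
  for (i in seq_len(ns)) {
    if (i == i_soma) next
    pi_ <- match(s$parent_id[i], s$id)
    child_rank[pi_] <- child_rank[pi_] + 1L
    rank <- child_rank[pi_]
    if (s$kind[pi_] == "soma") {
      th <- golden * (rank - 1); ph <- 0.9 * (rank %% 3 - 1)
      d <- c(cos(th) * cos(ph), sin(th) * cos(ph), sin(ph))
    } else {
      # rotate parent direction by a small deterministic angle
      pd <- dirs[pi_, ]
      ax <- if (abs(pd[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
      perp <- c(pd[2] * ax[3] - pd[3] * ax[2],
                pd[3] * ax[1] - pd[1] * ax[3],
                pd[1] * ax[2] - pd[2] * ax[1])
      perp <- perp / sqrt(sum(perp^2))
      ang <- 0.35 * (if (rank == 1) 1 else -1)
      d <- cos(ang) * pd + sin(ang) * perp
    }
    d <- d / sqrt(sum(d^2))
    dirs[i, ] <- d
    start <- distal_pos[pi_, ]
    parent_samp <- distal_samp[pi_]
    if (s$kind[pi_] == "soma") {
      parent_samp <- add(3, start, s$diam_prox[i] / 2, distal_samp[pi_])
    }
    end <- start + d * s$length[i]
    distal_samp[i] <- add(3, end, s$diam_dist[i] / 2, parent_samp)
    distal_pos[i, ] <- end
  }
  tab <- do.call(rbind, samples)
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   tab[, "id"], tab[, "type"], tab[, "x"], tab[, "y"],
                   tab[, "z"], tab[, "r"], tab[, "parent"])
  writeLines(c("# SWC morphology", paste0("# name: ", m$name), lines), path)
  invisible(path)
}

#' Read a morphology from an SWC file
#'
#' Parses the standard 7-column SWC format. Consecutive soma samples form a
#' single cylindrical soma section; every edge between two non-soma samples
#' becomes one tapered section. Edges from a soma sample to a dendrite sample
#' are attachments (the dendrite sample is the proximal end of a stem).
#'
#' @param path SWC file path
#' @return an `in_morphology`
#' @export
read_swc <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  rows <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(vapply(rows, length, integer(1)) != 7L)
  if (length(bad))
    stop("malformed SWC line ", lineno[bad[1]], " in ", path, call. = FALSE)
  tab <- matrix(as.numeric(unlist(rows)), ncol = 7, byrow = TRUE)
  if (anyNA(tab))
    stop("malformed SWC line ",
         lineno[which(apply(is.na(tab), 1, any))[1]], " in ", path,
         call. = FALSE)
  colnames(tab) <- c("id", "type", "x", "y", "z", "r", "parent")
  ids <- tab[, "id"]
  parent <- tab[, "parent"]
  roots <- which(parent == -1)
  if (length(roots) != 1L)
    stop("SWC parse error: expected exactly one root sample, found ",
         length(roots), call. = FALSE)
  known <- c(-1, ids)
  orphan <- which(!(parent %in% known))
  if (length(orphan))
    stop("SWC parse error at line ", lineno[orphan[1]],
         ": parent id ", parent[orphan[1]], " does not exist", call. = FALSE)
  if (tab[roots, "type"] != 1)
    stop("SWC parse error: root sample must be of soma type (1)",
         call. = FALSE)
  pidx <- match(parent, ids)          # NA for root
  # order samples parent-first
  ord <- order(ids)                   # assume file order is usable; verify
  for (i in seq_along(ids)) {
    if (!is.na(pidx[i]) && pidx[i] >= i)
      stop("SWC parse error: sample ", ids[i],
           " appears before its parent", call. = FALSE)
  }
  soma_samp <- which(tab[, "type"] == 1)
  # soma geometry
  if (length(soma_samp) == 1L) {
    L <- 2 * tab[soma_samp, "r"]; D <- L
  } else {
    seg_len <- vapply(soma_samp, function(i) {
      j <- pidx[i]
      if (is.na(j) || tab[j, "type"] != 1) return(0)
      sqrt(sum((tab[i, c("x", "y", "z")] - tab[j, c("x", "y", "z")])^2))
    }, numeric(1))
    L <- sum(seg_len)
    D <- 2 * mean(tab[soma_samp, "r"])
    if (L <= 0) { L <- 2 * tab[soma_samp[1], "r"]; D <- L }
  }
  secs <- list(data.frame(id = 1L, parent_id = NA_integer_, kind = "soma",
                          length = L, diam_prox = D, diam_dist = D,
                          nseg = 1L, stringsAsFactors = FALSE))
  # map: sample index -> section id owning its distal end
  samp_sec <- integer(nrow(tab))
  samp_sec[soma_samp] <- 1L
  next_id <- 2L
  for (i in seq_len(nrow(tab))) {
    if (tab[i, "type"] == 1) next
    j <- pidx[i]
    if (is.na(j))
      stop("SWC parse error: non-soma root sample", call. = FALSE)
    len <- sqrt(sum((tab[i, c("x", "y", "z")] - tab[j, c("x", "y", "z")])^2))
    if (tab[j, "type"] == 1 && len <= 1e-9) {
      # coincident child of a soma sample: attachment marker carrying the
      # proximal radius of a stem
      samp_sec[i] <- -i
      next
    }
    if (len <= 0)
      stop("SWC parse error at line ", lineno[i],
           ": zero-length edge", call. = FALSE)
    par_sec <- if (samp_sec[j] < 0) 1L else samp_sec[j]
    # proximal radius: from the parent sample, unless the parent is the soma
    # (stem attached at distance) in which case the stem's own radius applies
    r_prox <- if (tab[j, "type"] == 1) tab[i, "r"] else tab[j, "r"]
    secs[[next_id]] <- data.frame(id = next_id, parent_id = par_sec,
                                  kind = "dend", length = len,
                                  diam_prox = 2 * r_prox,
                                  diam_dist = 2 * tab[i, "r"],
                                  nseg = 1L, stringsAsFactors = FALSE)
    samp_sec[i] <- next_id
    next_id <- next_id + 1L
  }
  nm <- grep("^# name:", raw, value = TRUE)
  name <- if (length(nm)) trimws(sub("^# name:", "", nm[1])) else
    basename(path)
  new_morphology(do.call(rbind, secs), name = name)
}
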