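#' Tracer specification
#'
#' Describes a stable-isotope labeled precursor: which element carries the
#' label, how many heavy atoms the infused molecule carries, how many of
#' those are lost at the NAD+ incorporation step (the redox-active 4-position
#' deuterium of ring-deuterated nicotinamide), and the isotopic purity per
#' labeled position.
#'
#' @param name identifier, e.g. `"trp_13c11"`.
#' @param element labeled element, `"C"` or `"H"`.
#' @param n_heavy number of heavy atoms in the infused molecule.
#' @param entry metabolite id at which the tracer enters the network.
#' @param redox_site_loss heavy atoms lost upon incorporation into NAD+
#'   (0 for uniformly 13C-labeled tryptophan, 1 for ring-deuterated
#'   nicotinamide).
#' @param purity fraction in (0, 1]: probability that an intended-heavy
#'   position actually carries the heavy isotope.
#' @return object of class `tracer_spec`.
#' @export
tracer_spec <- function(name, element, n_heavy, entry,
                        redox_site_loss = 0L, purity = 0.99) {
  stopifnot(is.character(name), length(name) == 1L)
  element <- match.arg(element, c("C", "H"))
  n_heavy <- as.integer(n_heavy)
  redox_site_loss <- as.integer(redox_site_loss)
  if (n_heavy < 0L) stop("n_heavy must be >= 0")
  if (redox_site_loss < 0L || redox_site_loss > n_heavy)
    stop("redox_site_loss must satisfy 0 <= redox_site_loss <= n_heavy")
  if (!(purity > 0 && purity <= 1)) stop("purity must be in (0, 1]")
  structure(
    list(name = name, element = element, n_heavy = n_heavy, entry = entry,
         redox_site_loss = redox_site_loss, purity = purity),
    class = "tracer_spec"
  )
}

#' Uniformly 13C-labeled tryptophan tracer
#'
#' All 11 carbons heavy; no label loss at NAD+ incorporation.
#' @param purity per-position isotopic purity.
#' @export
tracer_trp13c <- function(purity = 0.99) {
  tracer_spec("trp_13c11", "C", 11L, "tryptophan",
              redox_site_loss = 0L, purity = purity)
}

#' Ring-deuterated (2,4,5,6-2H) nicotinamide tracer
#'
#' Four ring deuteriums; the redox-active 4-position deuterium is lost once
#' the molecule is incorporated into NAD+, so the M+4 infusate yields M+3
#' NAD+ and, upon NAD+ breakdown, M+3 recycled nicotinamide.
#' @param purity per-position isotopic purity.
#' @export
tracer_nam_d4 <- function(purity = 0.99) {
  tracer_spec("nam_d4", "H", 4L, "NAM", redox_site_loss = 1L, purity = purity)
}

#' Assemble a pathway map
#'
#' @param metabolites data.frame with columns `id`, `C`, `H`, `N`, `O`
#'   (element counts) and `routes` (comma-joined route tags).
#' @param transitions data.frame with columns `substrate`, `product`,
#'   `retained_C`, `retained_H` (atoms carried from substrate into product),
#'   `route`, `redox_edge` (logical: the NAD+ incorporation step where
#'   redox-site label loss applies) and `prior_route` (NA, or a route label
#'   the incoming path must have used last; encodes e.g. that luminal
#'   nicotinamide available to microbial deamidation is host-recycled).
#' @param tracers named list of [tracer_spec()] objects.
#' @param shift_overrides optional named integer vector replacing the
#'   computed shift for specific metabolites (reported-label conventions
#'   that differ from the structural atom count).
#' @return object of class `pathway_map`.
#' @export
pathway_map <- function(metabolites, transitions, tracers,
                        shift_overrides = integer()) {
  map <- structure(
    list(metabolites = metabolites, transitions = transitions,
         tracers = tracers, shift_overrides = shift_overrides),
    class = "pathway_map"
  )
  viol <- validate_map(map)
  if (length(viol)) stop("invalid pathway map: ", paste(viol, collapse = "; "))
  map
}

#' Default NAD+ metabolic atlas
#'
#' Metabolites and atom transitions of the de novo (kynurenine) pathway,
#' the nicotinamide salvage pathway, the Preiss-Handler route from nicotinic
#' acid, NAD+ consumption/recycling, nicotinamide methylation, and the
#' microbial deamidation of host-derived luminal nicotinamide. Molecular
#' formulas are standard chemistry. The 3-hydroxyanthranilic acid entry
#' carries its structural carbon count (7); a reported-label override (6) can
#' be installed via `shift_overrides` if a 6-carbon reading is wanted.
#'
#' @param tracers named list of tracers to attach; defaults to the
#'   uniformly 13C-labeled tryptophan and ring-deuterated nicotinamide
#'   tracers used in 20-h constant infusions.
#' @param shift_overrides see [pathway_map()].
#' @return a `pathway_map`.
#' @export
default_atlas <- function(tracers = list(trp_13c11 = tracer_trp13c(),
                                         nam_d4 = tracer_nam_d4()),
                          shift_overrides = integer()) {
  mets <- data.frame(
    id = c("tryptophan", "N-formylkynurenine", "kynurenine",
           "3-hydroxykynurenine", "anthranilic_acid",
           "3-hydroxyanthranilic_acid", "quinolinic_acid",
           "NaMN", "NaAD", "NAD", "NAM", "NMN", "nicotinic_acid",
           "MeNAM", "serotonin", "tryptamine", "indole_acetic_acid"),
    C = c(11, 11, 10, 10, 7, 7, 7, 11, 21, 21, 6, 11, 6, 7, 10, 10, 10),
    H = c(12, 12, 12, 12, 7, 7, 5, 14, 27, 27, 6, 15, 5, 8, 12, 12, 9),
    N = c(2, 2, 2, 2, 1, 1, 1, 1, 6, 7, 2, 2, 1, 2, 2, 2, 1),
    O = c(2, 4, 3, 4, 2, 3, 4, 9, 15, 14, 1, 8, 2, 1, 1, 0, 2),
    routes = c("de_novo", "de_novo", "de_novo", "de_novo", "kp_side",
               "de_novo", "de_novo", "de_novo,preiss_handler", "de_novo",
               "core", "salvage", "salvage", "preiss_handler,microbial",
               "methylation", "serotonin", "microbial_indole",
               "microbial_indole"),
    stringsAsFactors = FALSE
  )
  tr <- function(s, p, rc, rh, route, redox = FALSE, prior = NA_character_) {
    data.frame(substrate = s, product = p, retained_C = rc, retained_H = rh,
               route = route, redox_edge = redox, prior_route = prior,
               stringsAsFactors = FALSE)
  }
  trans <- rbind(
    # kynurenine (de novo) pathway: one C lost as formate at the formamidase
    # step, alanine (3 C) released at kynureninase, CO2 at QPRT
    tr("tryptophan", "N-formylkynurenine", 11, 10, "de_novo"),
    tr("N-formylkynurenine", "kynurenine", 10, 10, "de_novo"),
    tr("kynurenine", "3-hydroxykynurenine", 10, 10, "de_novo"),
    tr("kynurenine", "anthranilic_acid", 7, 5, "kp_side"),
    tr("3-hydroxykynurenine", "3-hydroxyanthranilic_acid", 7, 5, "de_novo"),
    tr("3-hydroxyanthranilic_acid", "quinolinic_acid", 7, 3, "de_novo"),
    tr("quinolinic_acid", "NaMN", 6, 3, "de_novo"),
    tr("NaMN", "NaAD", 11, 12, "de_novo"),
    tr("NaAD", "NAD", 21, 25, "de_novo"),
    # salvage: NAMPT then NMNAT; the redox-site deuterium is lost at
    # incorporation, modeled on the NAM -> NMN edge
    tr("NAM", "NMN", 6, 4, "salvage", redox = TRUE),
    tr("NMN", "NAD", 11, 14, "salvage"),
    # NAD+ consumption releases the nicotinamide moiety intact
    tr("NAD", "NAM", 6, 4, "recycling"),
    # methylation sink (NNMT)
    tr("NAM", "MeNAM", 6, 6, "methylation"),
    # microbial deamidation of host-recycled luminal NAM (bacterial PncA),
    # then Preiss-Handler re-entry
    tr("NAM", "nicotinic_acid", 6, 4, "microbial", prior = "recycling"),
    tr("nicotinic_acid", "NaMN", 6, 3, "preiss_handler"),
    # serotonin and microbial indole branches (monitored as shifts only)
    tr("tryptophan", "serotonin", 10, 10, "serotonin"),
    tr("tryptophan", "tryptamine", 10, 11, "microbial_indole"),
    tr("tryptophan", "indole_acetic_acid", 10, 7, "microbial_indole")
  )
  pathway_map(mets, trans, tracers, shift_overrides)
}

#' Validate a pathway map
#'
#' Checks that element counts are non-negative with positive carbon, that
#' every transition endpoint is a known metabolite, that retained atoms do
#' not exceed either endpoint's element count, that tracer invariants hold,
#' and that each named route's transition subgraph is acyclic.
#'
#' @param map a `pathway_map` (or bare list with the same fields).
#' @return character vector of violations; empty when the map is valid.
#' @export
validate_map <- function(map) {
  viol <- character()
  mets <- map$metabolites
  trans <- map$transitions
  if (any(mets$C <= 0)) {
    viol <- c(viol, paste("non-positive carbon count:",
                          paste(mets$id[mets$C <= 0], collapse = ",")))
  }
  for (el in c("C", "H", "N", "O")) {
    if (any(mets[[el]] < 0))
      viol <- c(viol, paste("negative", el, "count"))
  }
  idx <- match(trans$substrate, mets$id)
  if (anyNA(idx)) {
    viol <- c(viol, paste("unknown substrate:",
                          paste(unique(trans$substrate[is.na(idx)]),
                                collapse = ",")))
  }
  jdx <- match(trans$product, mets$id)
  if (anyNA(jdx)) {
    viol <- c(viol, paste("unknown product:",
                          paste(unique(trans$product[is.na(jdx)]),
                                collapse = ",")))
  }
  ok <- !is.na(idx) & !is.na(jdx)
  for (el in c("C", "H")) {
    ret <- trans[[paste0("retained_", el)]]
    bad <- ok & (ret > mets[[el]][idx] | ret > mets[[el]][jdx] | ret < 0)
    if (any(bad)) {
      viol <- c(viol, paste0("retained_", el, " exceeds formula: ",
                             paste(trans$substrate[bad], "->",
                                   trans$product[bad], collapse = "; ")))
    }
  }
  for (tracer in map$tracers) {
    if (tracer$redox_site_loss > tracer$n_heavy || tracer$redox_site_loss < 0)
      viol <- c(viol, paste("tracer", tracer$name, "redox_site_loss invalid"))
    if (!(tracer$purity > 0 && tracer$purity <= 1))
      viol <- c(viol, paste("tracer", tracer$name, "purity invalid"))
    if (!tracer$entry %in% mets$id)
      viol <- c(viol, paste("tracer", tracer$name, "entry not in atlas"))
  }
  # acyclicity per named route
  if (all(ok)) {
    for (r in unique(trans$route)) {
      sub <- trans[trans$route == r, , drop = FALSE]
      nodes <- unique(c(sub$substrate, sub$product))
      state <- stats::setNames(rep(0L, length(nodes)), nodes)
      cyc <- FALSE
      visit <- function(v) {
        if (state[[v]] == 1L) { cyc <<- TRUE; return(invisible()) }
        if (state[[v]] == 2L) return(invisible())
        state[[v]] <<- 1L
        for (w in sub$product[sub$substrate == v]) visit(w)
        state[[v]] <<- 2L
      }
      for (v in nodes) visit(v)
      if (cyc) viol <- c(viol, paste("route", r, "contains a cycle"))
    }
  }
  viol
}

# Shift of the product isotopologue given the substrate shift s along one
# transition. Atoms can only be lost (cap at atoms retained); the redox-site
# loss applies only to the intact infusate species (s == n_heavy), since a
# recycled molecule has already shed its redox-site label.
transition_shift <- function(s, transition, tracer) {
  retained <- transition[[paste0("retained_", tracer$element)]]
  out <- min(s, retained)
  if (isTRUE(transition$redox_edge) && tracer$redox_site_loss > 0L &&
      s == tracer$n_heavy) {
    out <- max(0L, out - tracer$redox_site_loss)
  }
  as.integer(out)
}

# Depth-first walk of the transition graph from the tracer entry point.
# Returns a data.frame (metabolite, shift, route) where route labels the
# edge that produced the metabolite ("tracer" for the entry molecule).
# Each path uses an edge at most once, which terminates the salvage/
# recycling cycle after one turn.
atlas_walk <- function(tracer, map) {
  trans <- map$transitions
  out <- data.frame(metabolite = tracer$entry, shift = tracer$n_heavy,
                    route = "tracer", stringsAsFactors = FALSE)
  recurse <- function(met, s, last_route, used) {
    cand <- which(trans$substrate == met & !used)
    for (k in cand) {
      pr <- trans$prior_route[k]
      if (!is.na(pr) && !identical(pr, last_route)) next
      s2 <- transition_shift(s, trans[k, ], tracer)
      out <<- rbind(out, data.frame(metabolite = trans$product[k],
                                    shift = s2, route = trans$route[k],
                                    stringsAsFactors = FALSE))
      used2 <- used
      used2[k] <- TRUE
      recurse(trans$product[k], s2, trans$route[k], used2)
    }
  }
  recurse(tracer$entry, tracer$n_heavy, "tracer",
          rep(FALSE, nrow(trans)))
  unique(out)
}

#' Expected isotopologue shift of a pathway product
#'
#' Walks the atom-transition graph from the tracer's entry metabolite and
#' returns the nominal mass shift(s) with which the query metabolite is
#' produced, applying the redox-site label loss exactly once at the NAD+
#' incorporation step. When several routes reach the metabolite (e.g. free
#' nicotinamide as intact infusate vs released by NAD+ breakdown) the
#' per-route set is returned; pass `route` to select one.
#'
#' @param tracer a [tracer_spec()].
#' @param metabolite metabolite id.
#' @param map a `pathway_map`.
#' @param route optional route label; returns a scalar shift for that route.
#' @return named integer vector of shifts (names are route labels), or a
#'   scalar integer when `route` is given.
#' @export
expected_shift <- function(tracer, metabolite, map = default_atlas(),
                           route = NULL) {
  if (!metabolite %in% map$metabolites$id)
    stop("metabolite '", metabolite, "' not in atlas")
  walk <- atlas_walk(tracer, map)
  hits <- walk[walk$metabolite == metabolite, , drop = FALSE]
  if (nrow(hits) == 0L)
    stop("no route from tracer '", tracer$name, "' to '", metabolite, "'")
  shifts <- stats::setNames(as.integer(hits$shift), hits$route)
  ov <- map$shift_overrides
  if (length(ov) && metabolite %in% names(ov)) {
    shifts[] <- as.integer(ov[[metabolite]])
  }
  if (!is.null(route)) {
    if (!route %in% names(shifts))
      stop("no route '", route, "' reaches '", metabolite, "'")
    return(unname(shifts[route]))
  }
  shifts[!duplicated(paste(names(shifts), shifts))]
}

#' Isotopologues to monitor for a tracer
#'
#' For every metabolite reachable from the tracer's entry point, the set of
#' nominal shifts the pipeline should extract: always M+0 plus every
#' route-resolved expected shift (e.g. nicotinamide under the ring-deuterated
#' tracer carries both the intact M+4 infusate and the M+3 species released
#' by NAD+ breakdown).
#'
#' @inheritParams expected_shift
#' @return named list: metabolite id -> sorted integer vector of shifts.
#' @export
monitored_isotopologues <- function(tracer, map = default_atlas()) {
  walk <- atlas_walk(tracer, map)
  mets <- unique(walk$metabolite)
  out <- lapply(mets, function(m) {
    s <- walk$shift[walk$metabolite == m]
    ov <- map$shift_overrides
    if (length(ov) && m %in% names(ov)) s <- as.integer(ov[[m]])
    sort(unique(c(0L, as.integer(s))))
  })
  stats::setNames(out, mets)
}

#' Write an atlas to a flat comma-separated text table
#'
#' One file with a `record` discriminator column holding metabolite rows
#' (id + formula + route tags), transition rows (endpoints, atoms retained,
#' route, flags) and tracer rows.
#'
#' @param map a `pathway_map`.
#' @param path output file.
#' @export
write_atlas <- function(map, path) {
  m <- map$metabolites
  met_rows <- data.frame(
    record = "metabolite", id = m$id, C = m$C, H = m$H, N = m$N, O = m$O,
    routes = m$routes, substrate = NA, product = NA, retained_C = NA,
    retained_H = NA, route = NA, redox_edge = NA, prior_route = NA,
    element = NA, n_heavy = NA, entry = NA, redox_site_loss = NA,
    purity = NA, stringsAsFactors = FALSE
  )
  t <- map$transitions
  tr_rows <- data.frame(
    record = "transition", id = NA, C = NA, H = NA, N = NA, O = NA,
    routes = NA, substrate = t$substrate, product = t$product,
    retained_C = t$retained_C, retained_H = t$retained_H, route = t$route,
    redox_edge = t$redox_edge, prior_route = t$prior_route,
    element = NA, n_heavy = NA, entry = NA, redox_site_loss = NA,
    purity = NA, stringsAsFactors = FALSE
  )
  tc_rows <- do.call(rbind, lapply(map$tracers, function(x) {
    data.frame(record = "tracer", id = x$name, C = NA, H = NA, N = NA,
               O = NA, routes = NA, substrate = NA, product = NA,
               retained_C = NA, retained_H = NA, route = NA,
               redox_edge = NA, prior_route = NA, element = x$element,
               n_heavy = x$n_heavy, entry = x$entry,
               redox_site_loss = x$redox_site_loss, purity = x$purity,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rbind(met_rows, tr_rows, tc_rows), path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an atlas written by [write_atlas()]
#'
#' @param path file path.
#' @return a `pathway_map`.
#' @export
read_atlas <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  m <- x[x$record == "metabolite", ]
  t <- x[x$record == "transition", ]
  tc <- x[x$record == "tracer", ]
  metabolites <- data.frame(id = m$id, C = m$C, H = m$H, N = m$N, O = m$O,
                            routes = m$routes, stringsAsFactors = FALSE)
  transitions <- data.frame(
    substrate = t$substrate, product = t$product, retained_C = t$retained_C,
    retained_H = t$retained_H, route = t$route,
    redox_edge = as.logical(t$redox_edge),
    prior_route = ifelse(is.na(t$prior_route) | t$prior_route == "",
                         NA_character_, t$prior_route),
    stringsAsFactors = FALSE
  )
  tracers <- stats::setNames(lapply(seq_len(nrow(tc)), function(i) {
    tracer_spec(tc$id[i], tc$element[i], tc$n_heavy[i], tc$entry[i],
                tc$redox_site_loss[i], tc$purity[i])
  }), tc$id)
  pathway_map(metabolites, transitions, tracers)
}
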