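---
title: "Measuring display and task fragmentation in EHR interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring display and task fragmentation in EHR interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrfrag)
```

## The problem

An EHR presents a tree of screens, menus and data elements. When the
information one clinical task needs is spread over many branches and levels
of that tree, the user must navigate — transition between screens, pick
entries from menus, scroll — and retain intermediate findings in working
memory. `ehrfrag` quantifies this *display fragmentation* from the
interface's structure alone, and the resulting *task fragmentation* from
what users actually did, via session event logs. This vignette documents
the model, every convention the implementation had to fix, and what the
bundled synthetic data can and cannot show.

## The navigation model

A `nav_tree` is the map produced by a *modified cognitive walkthrough*: the
analyst steps through all levels of the interface systematically and records
the menu structures and where each clinical data element lives, rather than
the steps of one specific task. Nodes carry:

* `kind` — `screen` (a display change), `menu_item` (a same-screen choice,
  e.g. a tab), or `data_element` (an item of clinical content, always a
  leaf);
* `is_target` — whether the node is relevant to the task under analysis
  (allowed on data elements and screens, not on menu items);
* `is_scrolling_screen` — whether the screen needs scrolling to be seen in
  full;
* `menu_length_override` — the number of parallel items actually displayed
  when it differs from the modelled children (real screens show entries that
  are not worth modelling as subtrees). Without an override, a node's menu
  length is its child count.

Depth 0 is the top-level screen. Two interchange dialects exist: a
path-per-row CSV (one row per leaf, plus rows for internal nodes with
non-default annotations; trailing blanks shorten a path, internal blanks are
rejected as ambiguous) and a nested JSON mirror of the node fields. Rows
merge by label within a parent, so sibling labels must be unique for the
CSV dialect; trees with repeated sibling labels are still representable
programmatically and in JSON, and the CSV serializer refuses them with a
pointer to the JSON dialect rather than silently conflating branches.

## The Display Fragmentation Index

For a target set, the package traces a deterministic pathway from the root
through every target and scores it:

`DFI = E + IS·X_IS + C·X_C + SS·X_SS + ML`

### Step conventions

The published definition leaves several countings open; the implementation
fixes them as follows, and each choice is visible in the API rather than
buried:

* **Target order.** Tree document order (depth-first, sibling order) unless
  the caller passes `in_order = TRUE`. Document order is reproducible and
  corresponds to reading the interface top-to-bottom, left-to-right.
* **Routing between targets** (`routing`). The unique simple path between
  two nodes of a tree bounces at their lowest common ancestor; this is the
  default (`"lca"`), and it is what the brute-force oracle in the test suite
  enumerates. `"root"` instead returns to the top screen between targets,
  re-entering and re-counting every intermediate screen — the maximal
  convention for interfaces where users reorient from the main screen each
  time. Both are "reasonable maximum" pathways in the sense that the path
  never uses shortcuts that are not in the tree.
* **Transitions vs clicks.** Entering a non-target screen counts one
  intermediate-screen transition *and* one click (the click that caused it);
  entering a menu item counts a click only (the display does not change).
  Arriving at a target counts one element access `E` and nothing else. This
  coupling is what makes the IS and C terms coincide on menu-free pathways,
  as they do in both worked examples below.
* **Scrolling.** Each entry into a scrolling screen adds exactly 2 scroll
  actions — an average over the variable length of such screens.
* **Target screens.** A screen flagged as a target is scored as an element
  access on first entry and is transparent afterwards. A consequence worth
  knowing: flagging an *element* as an additional target can only increase
  the index (this monotonicity is property-tested), whereas flagging an
  intermediate *screen* converts a weighted transition into an unweighted
  access and can lower it.
* **Menu length.** `ML` sums the effective menu length once per distinct
  decision point on the pathway — a traversed parent offering at least two
  parallel items. Unit menus (single forced continuation) present no choice
  and no visual search, so they carry no menu burden. Counting menus once
  rather than per traversal reflects that the burden measured is the
  complexity of choice at each stage, not repetition, which the transition
  terms already capture.
* **Multipliers** (`multiplier_policy`). `depth_weighted` (default) weights
  an action at level *l* by *l*, expressing that deep actions follow more
  prior navigation; `constant` (any positive value; 1 gives raw counts) is
  available when comparing systems whose depth should not be double-counted.
  `E` is never weighted.

### The worked examples

`demo_nav_tree()` ships two synthetic interfaces constructed so that the
traced pathway under the defaults reproduces two reference breakdowns
exactly:

```{r}
dfi(demo_nav_tree("dense"))
dfi(demo_nav_tree("integrated"))
compare_systems(dfi(demo_nav_tree("dense")), dfi(demo_nav_tree("integrated")))
```

The dense interface is a 16-screen spine with three 13-entry menus of
relevant results at depths 5, 10 and 16 (36 elements; weighted transition
and click terms of 1 + 2 + … + 16 = 136; menu burden 3 × 13 = 39). The
integrated one reaches a relevant summary screen at depth 8 and a 19-entry
review board at depth 10 (19 accesses, weighted terms 47, menu burden 19).
These are the package's regression anchors: the acceptance tests recompute
them through the full trace–tally–weight pipeline, never from stored
numbers.

## Session logs, ACT and PPI

A `session` is an ordered, non-overlapping set of segments
(`task`, `start_s`, `end_s`, optional `screen_id`), in seconds from session
start; absolute timestamps must be converted beforehand. Total EHR time is
the sum of segment durations by default — idle gaps are not EHR work — with
`total = "span"` available when wall-clock duration is wanted.

A **task instance** is a maximal run of consecutive same-label segments.
Abutting same-label segments merge; any gap splits (an interruption is an
interruption even if no other task was logged — configurable via
`split_on_gap = FALSE`). Then, per task:

* `ACT = total task time / n_instances` (seconds); and
* `PPI = total task time / (n_instances × total EHR time)`, equivalently
  `ACT / total EHR time`.

The PPI denominator uses the product of instance count and total time: the
measure must *fall* when the same task time is chopped into more pieces and
must not grow just because a session is long. Both properties are
unit-tested, along with exact conservation (task totals sum to the session
total) and invariance of PPI under uniform time rescaling.

## Visualizations

**Sunburst.** Concentric rings are hierarchy levels (ring = depth − 1; the
root is the centre disc), angular sectors are siblings. Default weighting is
`leaf_weighted` (arc proportional to leaf descendants, so heavy subtrees are
visually heavy); `equal_split` divides a parent equally. Angular boundaries
are computed cumulatively with the last child's end pinned to the parent's
end, so children partition their parent exactly in floating point and
conservation tests can assert identity, not approximation. Target nodes fill
black, traced pathways fill green via `highlight_pathway()`, and
`layout_sunburst_subtree()` re-roots a subtree for drill-down. Rendering is
fixed-format string assembly; identical layouts give byte-identical SVG.

**Time belt.** One horizontal row per session; each segment becomes a
rectangle at `start_s × scale` of width `duration × scale`, so belt length
is case duration and band count per colour is instance count. Colors come
from a fixed 20-colour qualitative palette assigned to *sorted* labels —
stable across rows, runs and sessions — cycling beyond 20. Gaps render as
unfilled space, exposing idle time. An absolute shared time scale is used
across rows so multi-system comparisons stay honest.

## Pogo-sticking and reporting

`detect_pogo_sticking()` collapses consecutive repeats of the segment key
(screen ids when recorded, task labels otherwise) and scans for maximal
alternating runs X, Y, X, Y, …, reporting a pair when each member occurs at
least `min_repeats` times (default 3), with the covering time window.
`build_report()` bundles DFI breakdowns (and the two-system comparison),
task summaries, pogo findings ranked into juxtaposition suggestions by the
time spent inside the alternation window — the largest recoverable time
first — and the figures; every number in the bundle is taken from the
underlying functions, never recomputed.

## The synthetic generators

`generate_nav_tree()` emulates walkthrough output: a complete tree of given
depth and (per-level) branching, all leaves data elements, targets placed
uniformly among leaves, scroll flags drawn per screen with `p_scroll`.
`generate_session()` emulates a task log as a Markov switching process: at
each `step_s`-second step the label switches with probability `p_switch` to
a uniformly chosen other label. Each call uses its own seeded RNG stream and
restores the caller's, so fixtures are byte-reproducible.

Defaults were chosen once as plausible study conditions: sessions of 120
steps of 5 s (ten-minute encounters), three to four task labels, switch
probabilities spanning 0.1–0.7, 50 seeds for response curves, 20 seeds for
DFI response checks, and property sweeps over random trees of up to 30
nodes with up to 4 targets. The generators reproduce the *mechanics* real
data exercises — hierarchy shapes, interleaved task runs, controllable
fragmentation — but not clinician behaviour: no task ontologies, no
duration heavy-tails, no correlation between where data lives and how users
move. Passing tests therefore demonstrate that the measures and layouts are
computed correctly and respond in the right direction (mean ACT and PPI
fall strictly as `p_switch` rises; mean DFI rises with depth and target
count), not that any particular real EHR scores any particular value.

## Numerical and degenerate-input choices

* All index arithmetic is integer counting plus small weighted sums; totals
  are exact and tested with `expect_equal` at default tolerance or
  `expect_identical` where integers are involved.
* Ties in target order are broken by sibling order; the pathway records the
  visit order actually taken, so results are reproducible.
* A comparison ratio is reported only when both totals are positive;
  per-term deltas are always reported.
* Empty target sets, unknown node ids, overlapping or end-before-start
  segments, annotation conflicts between table rows, ragged paths, and
  reports with neither trees nor sessions all raise immediate, named
  errors rather than propagating nonsense.
* An empty pathway tallies to all zeros and scores 0.

## Limitations

* The DFI pathway model assumes navigation follows tree edges; search boxes,
  keyboard shortcuts, bookmarks and user-specific routes are out of scope,
  so the index is an upper-bound style measure of structural burden.
* Whether a scrolling screen's hidden content is "the same level" is
  modelled as a flag (two scroll actions per visit), not as extra depth.
* The multiplier actually used in any published breakdown is a declared
  policy here, not something recoverable from a printed sum; comparisons
  should state the policy used, and the package defaults to depth weighting
  for both systems being compared.
* Session analysis trusts the log's segmentation; think-aloud or video
  evidence of within-segment activity is not modelled.
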