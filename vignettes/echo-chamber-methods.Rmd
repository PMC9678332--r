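---
title: "Measuring echo chambers: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring echo chambers: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echonet)
```

## The measurement problem

An echo chamber is a communication pattern, not a community label: users
interact predominantly with peers who share their topics of interest or
their attitude, so shared narratives reinforce themselves. `echonet`
operationalizes this for retweet/comment platforms with two complementary
network views built from the same corpus, then locates the individual users
who consolidate (echoers) or break (bridgers) the pattern.

The corpus is two tables. Each tweet carries a kind (`original`, `retweet`,
`comment`), a parent reference for interactions, a topic for originals
(13 categories organized by the Health Belief Model constructs —
susceptibility, severity, benefits, barriers, cues to action), and a
sentiment positive probability $\alpha \in [0,1]$ supplied by an upstream
sentiment model. Retweets and comments inherit the topic of the original at
the root of their parent chain; `validate_corpus()` enforces this and the
other structural invariants as data-level diagnostics rather than
exceptions.

## Networks

**Information layer** (undirected): nodes are original posts; the edge
weight between posts $i$ and $j$ is the number of *distinct* users who
interacted with both. Counting distinct users rather than interaction events
is deliberate: a single enthusiast retweeting both posts fifty times is one
shared audience member, not fifty.

**User layer** (directed): the edge $i \to j$ counts interactions where
$i$'s retweet/comment has a parent *authored by* $j$. We credit the
immediate parent's author, not the root original's: retweeting someone's
retweet is an interaction with the retweeter, and this is the reading under
which interaction chains stay local. Self-interactions are dropped (they
would corrupt clustering and constraint conventions), and users who
authored tweets but never interacted remain as isolated nodes by default
(`include_isolated = FALSE` restricts to touched users), since isolated
users are themselves an analytic category.

## Assortativity

For a categorical attribute, the mixing matrix $e_{ij}$ holds the fraction
of edge weight from category $i$ to category $j$ (undirected edges split
half and half), with marginals $a_i = \sum_j e_{ij}$, $b_j = \sum_i e_{ij}$,
and

$$r = \frac{\sum_i e_{ii} - \sum_i a_i b_i}{1 - \sum_i a_i b_i}.$$

Edge weights are used as multiplicities by default (`weighted = FALSE`
binarizes). The networks are weighted by construction, so the weighted
coefficient is the faithful summary; because reasonable analysts differ
here, `run_pipeline()` reports both. A graph whose edges all sit in one
category has $\sum a_i b_i = 1$; that case is returned as a flagged
degenerate result (`r = NA`), not an error.

## Burt's structural-hole indices

On symmetrized weights $z'_{ij} = z_{ij} + z_{ji}$, with proportional tie
strengths $p_{ij} = z'_{ij}/\sum_k z'_{ik}$:

* dyadic constraint $c_{ij} = (p_{ij} + \sum_{q \ne i,j} p_{iq} p_{qj})^2$,
  aggregate constraint $C_i = \sum_j c_{ij}$;
* effective size $S_i = N - \sum_j \sum_{q \ne j} p_{iq} m_{jq}$ with
  $m_{jq} = z'_{jq} / \max_k z'_{jk}$ and $q$ over ego's other contacts;
  efficiency $E_i = S_i/N$;
* hierarchy, the Coleman–Theil concentration
  $H_i = \sum_j \frac{c_{ij}}{C_i/N}\ln\frac{c_{ij}}{C_i/N} / (N \ln N)$,
  0 when constraint is spread evenly (and when $N=1$), 1 when concentrated
  on one contact.

Constraint is *not* clamped to $[0,1]$: small interlocked ego networks
legitimately exceed 1 (a triangle node has $C = 1.125$), and clamping would
break the closed-form checks the test suite relies on. Isolated egos get an
explicit undefined marker and are excluded from spanner candidacy.

## Roles

**Sentiment.** The printed three-way rules in circulation for discretizing
$\alpha$ are often inconsistent (overlapping intervals leave no neutral
region), so the package adopts a symmetric band: negative iff
$\alpha \le 0.4$, positive iff $\alpha \ge 0.6$, neutral between. Both
thresholds are exposed via `sentiment_band()`. A user's attitude is their
modal label; a tie means no dominant stance and resolves to neutral.

**Behavior taxonomy.** The criteria (speaker tiers at received/posted
ratios $\ge 100/10/3$; networker, monologist, retweeter, replicator rules
against population means; isolators with all four interaction counts zero)
are not mutually exclusive, so classification applies a fixed precedence —
automatic, isolator, speaker tiers, networker, monologist, retweeter,
replicator, common — ordered from most specific to least, influentials
before broadcasters. Two further conventions: "tweets" in ratio rules means
*original* tweets (the taxonomy distinguishes own tweets from retweets
sent), and any ratio with a zero denominator evaluates false rather than
erroring, so a user with no originals can never be a speaker no matter how
often they are retweeted. The tier threshold is read as $\ge 3\times$
(not $> 3\times$); the choice is visible and editable in one `case_when()`.

**Stakeholders.** Case-insensitive substring matching of a YAML keyword
lexicon (eleven types) against the concatenated profile text, first type in
lexicon order wins, `common_personnel` as fallback. The order matters —
"medical enterprise" must match *medical company* before the generic
"enterprise" of *common company* — and the shipped lexicon is ordered
accordingly.

**Echoers and bridgers.** Topic layer: echoer iff the user's created,
retweeted, and commented tweets span exactly one topic. Attitude layer:
echoer iff every interaction partner shares the *ego's* attitude
(ego-anchored reading; the alternative — partners merely agreeing with each
other — would be undefined for users with no partners, whereas the
ego-anchored rule makes isolators vacuously echoers, which is the behavior
the rest of the role system expects).

**Key users.** Leaders: top-5% cuts on weighted in-degree and local
clustering, combined by intersection. With one 5% cut leaders would be 5%
of users; the intersection is what reproduces leader shares an order of
magnitude below a single cut, as observed in large corpora. The union rule
is available (`leader_rule = "union"`) and both set sizes are always
reported. Cuts are rank-based with boundary ties included — deterministic
with no random tie-breaking. Spanners: bottom-5% constraint cut over all
non-isolated users first, then leaders removed, so the two key-user sets
are disjoint by construction.

**Statistics.** Support = joint count / group size; confidence = joint
count / topic-layer antecedent count; both kept at full precision with
rounding left to display. Chi-square is Pearson's without continuity
correction; posthoc diagnostics are adjusted standardized residuals with a
Bonferroni correction over cells, the standard contingency-table follow-up.
P-values below $10^{-15}$ are reported as that bound, with a `"<.001"`
display string preserved.

## The synthetic generator

The generator exists so that every estimator above can be validated without
any platform data. Its defaults encode the corpus conditions the analysis
assumes: attitude mixture 42.51% positive / 13.12% negative / rest neutral,
and a topic mixture whose top three shares are 24.46% / 20.40% / 16.46%.
Published sources for such corpora give only the top topic shares, so the
remaining ten topics decay geometrically (ratio 0.8) over the residual
38.68% — a free choice, fixed once here. Per-user activity counts are
negative binomial (size 1.2) around archetype means, a heavy-tailed shape
chosen in the absence of published per-user distributions; archetype
fractions default to 1% speakers, 3% networkers, 5% monologists, 8%
retweeters, 8% replicators, 15% isolators, 60% common.

Homophily is planted by a memoryless per-interaction mixture: with
probability $h$ the partner attribute equals the chooser's, else it is a
fresh draw from the marginal $\pi$. Then
$e_{ii} = \pi_i(h + (1-h)\pi_i)$ and $e_{ij} = (1-h)\pi_i\pi_j$, giving
$r = h$ exactly for *any* $\pi$ — the analytic oracle behind
`expected_assortativity()`. Keeping partner selection memoryless (no
preferential attachment beyond a fixed speaker popularity multiplier, which
is independent of attitude and therefore does not bias the mixture) is what
keeps this oracle exact. The oracle applies to the user layer; information-
layer assortativity under topic homophily is attenuated by co-audience
mixing and is deliberately not given a closed form.

Tweet sentiment is drawn from the band matching the author's latent
attitude with probability `label_fidelity` (default 1, i.e. a noiseless
sentiment model): sentiment-model noise and network structure are separate
concerns, and recovery tests should fail only for structural reasons. A
`p_deep` fraction of comments (default 0.15) attaches to a retweet rather
than an original, so two-step parent chains and immediate-parent crediting
are exercised; re-parenting targets only retweets, which keeps the tweet
reference graph acyclic by construction.

What the generator does **not** emulate: temporal dynamics, follower
graphs, content text, bursty cascades, bot behavior, or correlation between
attitude and activity level. Passing recovery tests therefore shows the
estimators are correct under planted homophily with heterogeneous activity
— not that real discourse satisfies the mixture model.

## Numerical and scale choices

Determinism: a fixed `(config, seed)` reproduces the corpus byte-for-byte
(`withr::with_seed` around each generation stage), and the pipeline is a
pure function of the corpus. Test and validation scales were chosen as the
smallest that make the stochastic checks meaningful: parameter recovery
uses $n = 5000$ users per homophily level (tolerance $\pm 0.05$, observed
error about an order of magnitude smaller), distributional checks use
4000–10000 users, and oracle-equivalence checks enumerate randomized graphs
of up to 8 nodes where brute-force triple loops are exact. Degenerate
inputs are contracts, not crashes: empty graphs and empty metric tables
raise typed errors, single-category graphs flag degeneracy, zero
association antecedents yield `NA` confidence.

## Known limitations

* The information-network builder materializes per-user co-interaction
  pairs; users interacting with hundreds of originals would make this
  quadratic in their audience size. Fine at the scales here; very large
  corpora would want a sparse co-occurrence accumulation.
* Stakeholder matching is substring-based and English-keyword shipped;
  real deployments should localize the lexicon (it is a plain YAML file).
* The `automatic` (bot-like) behavior category is wired through the
  classifier flags but never produced by the generator, so it is exercised
  only by unit fixtures.
* Graph exports preserve one node attribute and edge weights; the plain
  edge-list format carries structure and weights only.
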