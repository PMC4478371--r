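# Scenario file schema (version 1)

Scenarios are YAML or JSON (dispatch on extension; `.json` is parsed as
JSON, everything else as YAML). UTF-8, `.` decimal separator. Unknown
keys are rejected anywhere in the document.

## Top level

| key | type | required | default | notes |
|---|---|---|---|---|
| `schema_version` | int | yes | — | must be `1` |
| `description` | string | no | — | free-text provenance note |
| `strategies` | list | yes | — | see below |
| `survival` | mapping | yes | — | strategy name → `{os, pfs}` |
| `wtp_default` | number | no | 100000 | USD/QALY, > 0 |
| `cycle_length_months` | int | no | 1 | |
| `max_cycles` | int | no | 600 | lifetime-horizon cap |
| `discount_rate_annual` | number | no | 0 | applied as (1+r)^(−t/12) |
| `settings` | mapping | no | — | `anchor_month` (8), `half_cycle` (false), `ae_costs_on` (`alive`\|`stable`) |

## Distribution quadruples

Every uncertain quantity is `{base, low, high, family}` with
`low ≤ base ≤ high`. `family` ∈ `fixed | beta | gamma`; beta requires
`0 ≤ low` and `high ≤ 1`; gamma requires `low ≥ 0`. `low`/`high` default
to `base` (no range information); `family` defaults to `fixed`.

## Strategy entries

| key | type | required | notes |
|---|---|---|---|
| `name` | string | yes | unique |
| `monthly_drug_cost` | dist | yes | USD/month, gamma in practice |
| `utility_stable` | dist | yes | in [0,1], beta |
| `utility_progression` | dist | yes | in [0,1], beta |
| `crossover_monthly_cost` | number | no (0) | USD per unit progressed occupancy per cycle |
| `adverse_events` | list | no ([]) | see below |

Adverse event: `name`, `grade_band` (`g12`|`g34`),
`monthly_probability` (dist, beta), `management_cost` (dist, gamma, USD
per month on treatment), optional `ae_state_utility` in [0,1].

## Survival curves

Each strategy needs both `os` and `pfs`, either inline

```yaml
os:
  anchor_month: 8          # optional, default 8
  months: [0, 1, 2, ...]   # 0-based, step 1 (optional if survival given)
  survival: [1, 0.92, ...] # S(0) = 1, nonincreasing, in [0,1]
```

or as a CSV reference relative to the scenario file:

```yaml
os: {csv: curves/os_dabrafenib.csv}   # columns: month, survival
```

## Result CSVs

* `results.csv`: `name,total_cost,total_qaly`, rows sorted by cost
  ascending; costs at 2 decimals, QALYs at 6.
* `frontier.csv`: `name,total_cost,total_qaly,inc_cost,inc_qaly,icer,status`;
  ICERs at the nearest dollar; `status` ∈
  `frontier | dominated | extended_dominated`.
* `ceac.csv`: `wtp`, then one proportion column per strategy (rows sum
  to 1).
* `dsa.csv`: `value`, `cost_<s>`/`qaly_<s>` per strategy, `icer` of the
  swept strategy vs its comparator, `crossing` (interpolated value where
  the ICER equals the scenario threshold).
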