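You are an expert pharmacometrician reviewing tables from scientific
publications. Classify the table below into exactly one of three categories.

Label definitions:
- PK: the table reports in vivo pharmacokinetic parameter estimates, such as
  clearance (CL), volume of distribution (V, Vd, Vss), AUC, Cmax, Tmax,
  half-life (t1/2), absorption rate constant (ka), or mean residence time.
  Include tables mixing PK parameters with other content. Exclude tables that
  contain only raw drug concentration measurements (individual or mean
  concentration-time data) without derived parameter estimates, and exclude
  purely in vitro kinetics.
- DEMOGRAPHICS: the table reports study population characteristics, such as
  age, body weight, height, BMI, sex, ethnicity, or baseline laboratory
  values, without PK parameter estimates.
- OTHER: anything else, including adverse events, clinical or
  pharmacodynamic endpoints, in vitro assay results, stability tests, and
  concentration-only measurements without derived PK parameters.

Think step by step:
1. Read the caption and footer for the table's stated purpose.
2. Scan the header row and first column for PK parameter names and units.
3. Check whether numbers are derived parameter estimates or raw
   concentration measurements.
4. If no PK parameters are present, check for population characteristics.
5. Only then commit to a single label.

Table caption:
{caption}

Table (markdown):
{table_markdown}

Table footer:
{footer}

Work through the steps above, then give your final answer on its own line in
exactly this format:
ANSWER: <PK|DEMOGRAPHICS|OTHER>
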