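# Benchmark coverage-study design: 48 (pi, se, sp) combinations crossed
# with 3 accuracy-study sizes and 3 prevalence-study sizes (432 cells).
pi: [0.05, 0.25, 0.5]
se: [0.5, 0.75, 0.85, 0.9]
sp: [0.5, 0.75, 0.85, 0.9]
n: [50, 100, 500]
mg: [100, 500, 1000]
reps: 10000
alpha: 0.05
sides: [PPV, NPV]
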