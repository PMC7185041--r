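quantity,value
total_adult_captures,18799
initial_ahy_captures,4754
redetermined_to_sy_asy,3131
n_individuals,12714
n_year_unique,13790
n_stations,35
n_years,6
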