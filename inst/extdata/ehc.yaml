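# Gallbladder emptying / enterohepatic recirculation parameters.
emptying_half_time: 41.44     # min, exponential release half-time
continuous_fraction: 0.1      # bile fraction continuously entering duodenum
ejection_fraction: 0.45       # fraction of stored bile ejected per meal event
refill_time: 241.0            # min, time to complete gallbladder refilling
meal_times: [4.0, 10.0, 15.0] # h post morning dose; repeats every 24 h
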