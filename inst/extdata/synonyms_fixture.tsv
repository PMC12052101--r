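amount	amount,bar,bill,cadence,criterion,measure,measurement,meter,metre,quantity,standard,step,touchstone
bar	amount,bar,bill,cadence,criterion,measure,measurement,meter,metre,quantity,standard,step,touchstone
bill	amount,bar,bill,cadence,criterion,measure,measurement,meter,metre,quantity,standard,step,touchstone
cadence	amount,bar,bill,cadence,criterion,measure,measurement,meter,metre,quantity,standard,step,touchstone
criterion	amount,bar,bill,cadence,criterion,measure,measurement,meter,metre,quantity,standard,step,touchstone
measure	amount,bar,bill,cadence,criterion,measure,measurement,meter,metre,quantity,standard,step,touchstone
measurement	amount,bar,bill,cadence,criterion,measure,measurement,meter,metre,quantity,standard,step,touchstone
meter	amount,bar,bill,cadence,criterion,measure,measurement,meter,metre,quantity,standard,step,touchstone
metre	amount,bar,bill,cadence,criterion,measure,measurement,meter,metre,quantity,standard,step,touchstone
quantity	amount,bar,bill,cadence,criterion,measure,measurement,meter,metre,quantity,standard,step,touchstone
standard	amount,bar,bill,cadence,criterion,measure,measurement,meter,metre,quantity,standard,step,touchstone
step	amount,bar,bill,cadence,criterion,measure,measurement,meter,metre,quantity,standard,step,touchstone
touchstone	amount,bar,bill,cadence,criterion,measure,measurement,meter,metre,quantity,standard,step,touchstone
13	13,thirteen,xiii
thirteen	13,thirteen,xiii
xiii	13,thirteen,xiii
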