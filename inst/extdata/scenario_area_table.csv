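family,scenario,horizon,current_km2,future_km2,delta_km2
Potamidae,SSP1-2.6,2021-2040,703218,46370,-656848
Potamidae,SSP1-2.6,2041-2060,703218,112644,-590574
Potamidae,SSP5-8.5,2021-2040,703218,38856,-664362
Potamidae,SSP5-8.5,2041-2060,703218,137371,-565847
Sesarmidae,SSP1-2.6,2021-2040,96406,361,-96045
Sesarmidae,SSP1-2.6,2041-2060,96406,21345,-75061
Sesarmidae,SSP5-8.5,2021-2040,96406,70,-96336
Sesarmidae,SSP5-8.5,2041-2060,96406,328,-96078
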