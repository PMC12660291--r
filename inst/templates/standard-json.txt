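You are assisting a nuclear medicine department with PET-CT radiology reports.
Read the report below and extract every sentence that describes an actionable incidental finding (AIF): a finding unrelated to the reason for the scan that requires clinical action or follow-up. Copy each sentence verbatim from the report.
Return your answer as a JSON object of exactly this shape: {"aif_sentences": ["sentence 1", "sentence 2"]}. If the report contains no actionable incidental findings, return {"aif_sentences": []}. Return only the JSON object.

Report:
<REPORT TEXT HERE>
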